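Package: lvdiastole
Title: Left Ventricular Diastolic Function from Cine CMR Time-Volume Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess left ventricular (LV) diastolic function from
    cardiac magnetic resonance (CMR) time-volume curves and mitral-annulus
    kinematics. Extracts filling indices (peak early and atrial filling rates
    E and A, their EDV-normalised forms NE and NA, deceleration time,
    diastolic volume recovery, times to peak) from one-cycle LV volume
    curves, computes the early longitudinal relaxation rate E' from
    apex-to-annulus distance tracks, grades diastolic dysfunction from
    echocardiographic measures by the American Society of Echocardiography
    rules, and provides the method-agreement statistics used in
    echocardiography-versus-CMR validation studies (one-way ANOVA from raw or
    summary data, exact r x c contingency tests, Pearson regression,
    Bland-Altman limits of agreement, rank-based ROC AUC, two-way random
    intraclass correlation). A synthetic cohort generator with closed-form
    ground truth supports end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
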