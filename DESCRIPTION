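Package: canspec
Title: Cell Adhesion Noise Spectroscopy for CMOS Microelectrode Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free electrical imaging of adherent cells on high-density
    CMOS microelectrode arrays from the thermal voltage noise of the
    cell-chip cleft. Provides Welch spectral estimation of per-sensor
    voltage-noise power, bare-sensor background subtraction to obtain the
    cell adhesion noise, Johnson-Nyquist conversion between adhesion noise
    and cleft resistance, Otsu-based segmentation of electrical images into
    cell-covered area, multi-chip drug-response time-course quantification,
    and a physics-grounded simulator of array noise recordings (cell
    layouts, 1/f plus white backgrounds, adhesion-noise plateaus,
    proliferation and detachment dynamics) with exported ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
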