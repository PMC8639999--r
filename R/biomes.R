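#' Terrestrial Ecoregions of the World biome vocabulary
#'
#' The 14 major TEOW biome types used to stratify per-biome standardization,
#' with short codes and a tropical/subtropical classification. The
#' classification is decided by biome name: any biome whose name contains
#' "Tropical" or "Subtropical", plus Mangroves, counts as (sub)tropical and is
#' exempt from seasonal standardization.
#'
#' @return A data frame with columns `code`, `name`, and
#'   `is_subtropical_or_tropical` (logical), one row per biome.
#' @examples
#' bt <- biome_table()
#' sum(bt$is_subtropical_or_tropical)  # 5 (sub)tropical biomes
#' @export
biome_table <- function() {
  bt <- data.frame(
    code = c("TSMF", "TSDF", "TSCF", "TBMF", "TCF", "BFT", "TSGS",
             "TGSS", "FGS", "MGS", "TUN", "MFWS", "DXS", "MAN"),
    name = c(
      "Tropical & Subtropical Moist Broadleaf Forests",
      "Tropical & Subtropical Dry Broadleaf Forests",
      "Tropical & Subtropical Coniferous Forests",
      "Temperate Broadleaf & Mixed Forests",
      "Temperate Conifer Forests",
      "Boreal Forests/Taiga",
      "Tropical & Subtropical Grasslands, Savannas & Shrublands",
      "Temperate Grasslands, Savannas & Shrublands",
      "Flooded Grasslands & Savannas",
      "Montane Grasslands & Shrublands",
      "Tundra",
      "Mediterranean Forests, Woodlands & Scrub",
      "Deserts & Xeric Shrublands",
      "Mangroves"
    ),
    stringsAsFactors = FALSE
  )
  bt$is_subtropical_or_tropical <-
    grepl("tropical", bt$name, ignore.case = TRUE) | bt$code == "MAN"
  bt
}

#' Biome codes
#'
#' @return Character vector of the 14 TEOW biome codes.
#' @export
biome_codes <- function() biome_table()$code

#' Codes of (sub)tropical biomes
#'
#' Biomes exempt from seasonal standardization (low seasonality).
#'
#' @return Character vector of biome codes.
#' @export
tropical_biome_codes <- function() {
  bt <- biome_table()
  bt$code[bt$is_subtropical_or_tropical]
}

#' Names of the 31 environmental predictors
#'
#' The fixed predictor vocabulary: 19 bioclimatic indices, 8 topsoil
#' variables, human footprint, net primary productivity, plant diversity, and
#' absolute latitude.
#'
#' @return Character vector of length 31.
#' @export
predictor_names <- function() {
  c("abs.latit", "AMT", "AP", "ATR", "AVWAC", "BULK", "CEC", "CLAYC",
    "diversity", "HFP", "Isoth", "npp", "ORGNC", "PCQ", "PDM", "PDQ",
    "pH", "Pseason", "PWeQ", "PWM", "PWQ", "SANDC", "SILTC", "TCM",
    "TCQ", "TDQ", "TDR", "Tseason", "TWeQ", "TWM", "TWQ")
}

# Plausible ranges used for validation and synthetic generation.
# Percentages in [0,100]; pH in water; temperatures in degC; precipitation mm.
predictor_ranges <- function() {
  list(
    `abs.latit` = c(0, 90),   AMT = c(-20, 30),   AP = c(0, 4000),
    ATR = c(5, 60),           AVWAC = c(0, 100),  BULK = c(300, 1800),
    CEC = c(0, 60),           CLAYC = c(0, 100),  diversity = c(0, 10),
    HFP = c(0, 50),           Isoth = c(10, 100), npp = c(0, 2000),
    ORGNC = c(0, 200),        PCQ = c(0, 1200),   PDM = c(0, 200),
    PDQ = c(0, 600),          pH = c(3.5, 9.5),   Pseason = c(0, 150),
    PWeQ = c(0, 2000),        PWM = c(0, 800),    PWQ = c(0, 1500),
    SANDC = c(0, 100),        SILTC = c(0, 100),  TCM = c(-45, 25),
    TCQ = c(-35, 28),         TDQ = c(-30, 32),   TDR = c(3, 22),
    Tseason = c(0, 1800),     TWeQ = c(-15, 32),  TWM = c(5, 45),
    TWQ = c(-5, 35)
  )
}
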