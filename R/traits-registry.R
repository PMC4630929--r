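# The 78-trait registry: ids, categories and units. Four categories
# cover all root system architectures (common), monocot crowns, dicot
# (taproot) crowns, and excised root samples.

#' The trait registry
#'
#' Enumerates all 78 measurable traits with their category (`common`,
#' `monocot`, `dicot`, `excised`) and units (`mm`, `mm2`, `degrees`,
#' `count`, `dimensionless`, `per_mm`). Length and area units degrade to
#' px / px2 when no scale marker is present in a scene.
#'
#' @return a tibble with columns `trait`, `category`, `unit`.
#' @examples
#' nrow(trait_registry())  # 78
#' @export
trait_registry <- function() {
  common <- tibble(
    trait = c("AREA", "AVG_DENSITY", "WIDTH_MED", "WIDTH_MAX",
              "DIA_STM", "DIA_STM_SIMPLE", "ANG_TOP", "ANG_BTM",
              "SKL_DEPTH", "SKL_WIDTH", "RTP_COUNT", "RDISTR_X", "RDISTR_Y",
              paste0("D", seq(10, 90, 10)), paste0("DS", seq(10, 90, 10))),
    category = "common",
    unit = c("mm2", "dimensionless", "mm", "mm", "mm", "mm",
             "degrees", "degrees", "mm", "mm", "count",
             "dimensionless", "dimensionless",
             rep("dimensionless", 18))
  )
  monocot <- tibble(
    trait = c("STA_RANGE", "STA_DOM_I", "STA_DOM_II",
              "STA_25_I", "STA_25_II", "STA_50_I", "STA_50_II",
              "STA_75_I", "STA_75_II", "STA_90_I", "STA_90_II",
              "RTA_RANGE", "RTA_DOM_I", "RTA_DOM_II",
              "NR_RTP_SEG_I", "NR_RTP_SEG_II",
              "CP_DIA25", "CP_DIA50", "CP_DIA75", "CP_DIA90",
              "MAX_DIA_90", "DROP_50"),
    category = "monocot",
    unit = c(rep("degrees", 14), "count", "count",
             rep("mm", 5), "dimensionless")
  )
  dicot <- tibble(
    trait = c("ADVT_COUNT", "BASAL_COUNT", "ADVT_ANG", "BASAL_ANG",
              "HYP_DIA", "TAP_DIA", "LT_BRA_FRQ", "LT_AVG_LEN",
              "LT_DIST_FIRST", "LT_MED_DIA", "LT_AVG_DIA",
              "LT_AVG_ANG", "LT_ANG_RANGE", "LT_MIN_ANG", "LT_MAX_ANG"),
    category = "dicot",
    unit = c("count", "count", "degrees", "degrees", "mm", "mm",
             "per_mm", "mm", "mm", "mm", "mm",
             "degrees", "degrees", "degrees", "degrees")
  )
  excised <- tibble(
    trait = c("EXC_SEG_COUNT", "EXC_TOT_LEN", "EXC_AVG_LEN", "EXC_MED_LEN",
              "EXC_MAX_LEN", "EXC_AVG_DIA", "EXC_MED_DIA", "EXC_BRA_FRQ",
              "EXC_TIP_COUNT", "EXC_AREA"),
    category = "excised",
    unit = c("count", "mm", "mm", "mm", "mm", "mm", "mm",
             "per_mm", "count", "mm2")
  )
  dplyr::bind_rows(common, monocot, dicot, excised)
}

# A fresh all-NA partial record for a set of trait ids.
empty_record <- function(ids, status = "computation-failed") {
  tibble(trait = ids, value = NA_real_, status = status)
}

ok_trait <- function(trait, value) {
  tibble(trait = trait,
         value = as.double(value),
         status = ifelse(is.na(value), "computation-failed", "ok"))
}

na_trait <- function(trait, status) {
  tibble(trait = trait, value = NA_real_, status = status)
}
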