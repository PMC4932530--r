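#' Suitable-pixel counts for 35 Macaronesian endemic bryophytes
#'
#' Reported numbers of ~1 km2 climatically suitable pixels per species in
#' Macaronesia (`n_mac_*`) and in western Europe / northwestern Africa
#' (`n_cont_*`) under present climate and under 2070 conditions for a
#' mitigated (RCP 4.5) and a high-emission (RCP 8.5) concentration pathway,
#' together with the percentages relative to the present situation as
#' printed (`pct_*`; `NA` where no present suitable area exists). Bundled as
#' the worked example for the range-change arithmetic and its headline
#' summaries.
#'
#' @return tibble with 35 rows and columns `species`, `n_mac_present`,
#'   `n_cont_present`, and count/percentage pairs for each scenario and
#'   region.
#' @export
bryophyte_suitable_pixels <- function() {
  path <- system.file("extdata", "bryophyte_suitable_pixels.csv",
                      package = "bryoclim", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
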