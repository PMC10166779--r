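# Published registry reference values shipped as plain-text data.
#
# These are the printed summary estimates from the prospective Lynch
# syndrome database (PLSD) registry report: per-organ 10-year crude
# survival, cumulative incidence at 65 by gene and sex with the displayed
# mortality at 75, and the death counts by cancer type and gene.  They are
# inputs for desk-scale reproduction of the derived statistics -- the
# individual-level registry data are not public.

#' Published mortality reference table
#'
#' Per (organ, gene, sex): the published 10-year crude survival (`s10_pct`),
#' cumulative incidence at 65 years (`q65_pct`) and the displayed crude
#' mortality at 75 (`m75_pct`, integer percent).  Sex-specific organs carry
#' only the applicable sex.
#'
#' @return A data frame with columns `organ`, `gene`, `sex`, `s10_pct`,
#'   `q65_pct`, `m75_pct`.
#' @export
ref_mortality_table <- function() {
  read.csv(system.file("extdata", "mortality_reference.csv",
                       package = "lynchrisk"),
           stringsAsFactors = FALSE)
}

#' Published death counts by cancer type and gene
#'
#' Per (organ, gene): the published number of carriers with a prospective
#' cancer in the organ (`n`) and the number of them dead at last
#' observation (`n_deaths`).
#'
#' @return A data frame with columns `organ`, `gene`, `n`, `n_deaths`.
#' @export
ref_death_counts <- function() {
  read.csv(system.file("extdata", "death_counts_reference.csv",
                       package = "lynchrisk"),
           stringsAsFactors = FALSE)
}
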