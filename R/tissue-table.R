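# Bundled tissue dielectric parameter table.

#' Load a tissue Cole-Cole parameter table
#'
#' Reads a CSV with one row per tissue and columns
#' `tissue, eps_inf, delta_eps1, tau1, alpha1, delta_eps2, tau2, alpha2,
#' sigma, c_sigma, c_delta_eps1` into a named list of entries, each holding a
#' [cole_cole_params()] set and its [temperature_coefficients()]. Lines
#' starting with `#` are comments.
#'
#' The table bundled with the package
#' (`inst/extdata/tissue_params_synthetic.csv`) carries synthetic stand-in
#' values in the style of published tissue-dielectric compilations; its
#' numbers are fixture data for the simulated study, not measurements.
#'
#' @param path CSV file; default the bundled synthetic table.
#' @return named list of class `tissue_table`; each element has `$params` and
#'   `$coeffs`.
#' @examples
#' tab <- load_tissue_table()
#' names(tab)
#' cole_cole(tab$muscle$params, 1.35e9)
#' @export
load_tissue_table <- function(path = system.file("extdata",
                                                 "tissue_params_synthetic.csv",
                                                 package = "thermowave")) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("tissue", "eps_inf", "delta_eps1", "tau1", "alpha1",
            "delta_eps2", "tau2", "alpha2", "sigma", "c_sigma",
            "c_delta_eps1")
  if (!all(need %in% names(df))) {
    stop("tissue table is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  tab <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    list(params = cole_cole_params(r$eps_inf, r$delta_eps1, r$delta_eps2,
                                   r$tau1, r$tau2, r$alpha1, r$alpha2,
                                   r$sigma),
         coeffs = temperature_coefficients(delta_eps1 = r$c_delta_eps1,
                                           sigma = r$c_sigma))
  })
  names(tab) <- df$tissue
  structure(tab, class = "tissue_table")
}
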