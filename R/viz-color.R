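#' Diverging correlation color scale
#'
#' Maps r in [-1, 1] to a red-white-blue diverging scale: -1 pure red,
#' 0 white, +1 pure blue, linear in between, clamped at the endpoints.
#' The scale is odd-symmetric: the color of -r is the red/blue mirror of
#' the color of r.
#'
#' @param r numeric vector of correlation coefficients.
#' @return character vector of hex colors.
#' @export
correlation_color <- function(r) {
  r <- pmin(pmax(as.numeric(r), -1), 1)
  vapply(r, function(v) {
    if (v < 0) grDevices::rgb(1, 1 + v, 1 + v) else grDevices::rgb(1 - v, 1 - v, 1)
  }, character(1))
}

sbgn_default_fill <- function(cls) {
  switch(cls,
         simple_chemical = "#ccffcc", macromolecule = "#ffddaa",
         process = "#ffffff", compartment = "#eeeeee", "#dddddd")
}
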