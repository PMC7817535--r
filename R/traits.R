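## Trait derivation: the V182 stem volume equation.

#' Stem volume from DBH and height (V182)
#'
#' The standard New Zealand radiata pine total stem volume equation:
#' `V = DBH^a * (H^2 / (H - 1.4))^b * exp(c)` with `a = 1.79068`,
#' `b = 1.07473`, `c = -10.03201`; DBH in centimetres, H in metres, V in
#' cubic metres. The height term is singular at breast height (1.4 m), so
#' heights at or below 1.4 m are a domain error.
#'
#' @param dbh diameter at breast height, cm (> 0).
#' @param h total height, m (> 1.4).
#' @return stem volume, m^3 (vectorised; `NA` in, `NA` out).
#' @examples
#' compute_volume(20, 15) # ~0.192 m^3
#' @export
compute_volume <- function(dbh, h) {
  a <- 1.79068; b <- 1.07473; cc <- -10.03201
  ok <- !is.na(dbh) & !is.na(h)
  if (any(dbh[ok] <= 0))
    stop("`dbh` must be positive", call. = FALSE)
  if (any(h[ok] <= 1.4))
    stop("`h` must exceed breast height (1.4 m): V182 is singular there",
         call. = FALSE)
  dbh^a * (h^2 / (h - 1.4))^b * exp(cc)
}
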