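#' Dendritic vertical bias
#'
#' Fraction of total dendritic length oriented within `tolerance_deg` of
#' vertical (the axis perpendicular to the pial surface). Segment angles
#' are direction-agnostic (folded to 0-90 degrees from vertical), and
#' each segment contributes its length. A perfectly bipolar cell scores
#' 1; an isotropic arbor scores about 1/3 (60 of 180 degrees).
#'
#' @param segments data.frame (or matrix) with columns `x0, y0, x1, y1`
#'   in um; the y axis is perpendicular to the pia.
#' @param tolerance_deg angular tolerance from vertical, degrees.
#' @return Fraction in `[0, 1]`.
#' @examples
#' vertical_bias(data.frame(x0 = 0, y0 = 0, x1 = 0, y1 = 50)) # 1
#' @export
vertical_bias <- function(segments, tolerance_deg = 30) {
  segments <- as.data.frame(segments)
  need <- c("x0", "y0", "x1", "y1")
  if (!all(need %in% names(segments))) {
    if (ncol(segments) >= 4) names(segments)[1:4] <- need
    else stop("segments must have columns x0, y0, x1, y1")
  }
  dx <- segments$x1 - segments$x0
  dy <- segments$y1 - segments$y0
  len <- sqrt(dx^2 + dy^2)
  if (!nrow(segments) || sum(len) == 0) stop("trace has zero total length")
  keep <- len > 0
  dx <- dx[keep]; dy <- dy[keep]; len <- len[keep]
  angle <- atan2(abs(dx), abs(dy)) * 180 / pi  # 0 = vertical, 90 = horizontal
  sum(len[angle <= tolerance_deg]) / sum(len)
}

#' Read a dendrite trace from CSV
#'
#' Expects one polyline segment per row with columns `x0,y0,x1,y1` (um).
#'
#' @param path CSV file path.
#' @return data.frame of segments suitable for [vertical_bias()].
#' @export
read_dendrite_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x0", "y0", "x1", "y1") %in% names(df)))
    stop("dendrite CSV must have columns x0, y0, x1, y1")
  df
}
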