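#' Standard 3x5 prefrontal optode montage
#'
#' Builds the standard prefrontal grid: 3 rows x 5 columns of optodes in
#' checkerboard alternation (8 sources, 7 detectors), worn with row 1 just
#' above the eyebrows and row 3 approximately along the F5-Fz-F6 line of the
#' 10-20 system. Every grid-adjacent source-detector pair, at 3 cm
#' separation, is a measurement channel; the 3x5 grid graph has 12 horizontal
#' and 10 vertical adjacencies, hence 22 channels.
#'
#' Channel numbering is fixed and documented: channels are ordered by the
#' vertical position of their midpoint from the bottom row upward, and left
#' to right within a band. Concretely: channels 1-4 are the bottom-row
#' horizontal pairs (channels 2 and 3 sit approximately over Fp1 and Fp2),
#' 5-9 the verticals between rows 1 and 2, 10-13 the middle-row horizontals,
#' 14-18 the verticals between rows 2 and 3, and 19-22 the top-row
#' horizontals.
#'
#' @param spacing_cm Optode separation in cm (default 3).
#' @return An object of class `fnirs_montage`: a list with `optodes`
#'   (data frame: `optode`, `type`, `row`, `col`) and `channels`
#'   (data frame: `channel`, `source`, `detector`, `row_mid`, `col_mid`,
#'   `separation_cm`, `region`).
#' @examples
#' m <- build_standard_montage()
#' nrow(m$channels)  # 22
#' @export
build_standard_montage <- function(spacing_cm = 3) {
  grid <- expand.grid(row = 1:3, col = 1:5)
  # checkerboard: sources where row+col is even (8 of 15), detectors otherwise
  grid$type <- ifelse((grid$row + grid$col) %% 2 == 0, "source", "detector")
  grid <- grid[order(grid$row, grid$col), ]
  grid$optode <- ave(seq_len(nrow(grid)), grid$type, FUN = seq_along)
  grid$optode <- paste0(ifelse(grid$type == "source", "S", "D"), grid$optode)

  edge <- function(r1, c1, r2, c2) {
    a <- grid[grid$row == r1 & grid$col == c1, ]
    b <- grid[grid$row == r2 & grid$col == c2, ]
    src <- if (a$type == "source") a$optode else b$optode
    det <- if (a$type == "detector") a$optode else b$optode
    data.frame(source = src, detector = det,
               row_mid = (r1 + r2) / 2, col_mid = (c1 + c2) / 2)
  }
  edges <- list()
  for (r in 1:3) for (cc in 1:4) edges[[length(edges) + 1L]] <- edge(r, cc, r, cc + 1)
  for (r in 1:2) for (cc in 1:5) edges[[length(edges) + 1L]] <- edge(r, cc, r + 1, cc)
  ch <- do.call(rbind, edges)
  ch <- ch[order(ch$row_mid, ch$col_mid), ]
  ch$channel <- seq_len(nrow(ch))
  ch$separation_cm <- spacing_cm
  ch$region <- montage_region(ch$row_mid, ch$col_mid)
  rownames(ch) <- NULL
  ch <- ch[, c("channel", "source", "detector", "row_mid", "col_mid",
               "separation_cm", "region")]

  structure(list(optodes = grid[, c("optode", "type", "row", "col")],
                 channels = ch, spacing_cm = spacing_cm),
            class = "fnirs_montage")
}

# approximate 10-20-flavoured region labels; row 1 = above eyebrows
montage_region <- function(row_mid, col_mid) {
  side <- ifelse(col_mid < 3, "L", ifelse(col_mid > 3, "R", "mid"))
  band <- ifelse(row_mid <= 1, "frontopolar",
          ifelse(row_mid <= 2, "vlPFC", "dlPFC"))
  lab <- paste0(band, "-", side)
  lab[row_mid == 1 & col_mid == 2.5] <- "Fp1"
  lab[row_mid == 1 & col_mid == 3.5] <- "Fp2"
  lab
}

#' @export
print.fnirs_montage <- function(x, ...) {
  cat("fNIRS montage: 3x5 optode grid,",
      sum(x$optodes$type == "source"), "sources,",
      sum(x$optodes$type == "detector"), "detectors,",
      nrow(x$channels), "channels at", x$spacing_cm, "cm separation\n")
  invisible(x)
}

validate_montage <- function(m) {
  stopifnot(inherits(m, "fnirs_montage"))
  ok_s <- m$channels$source %in% m$optodes$optode[m$optodes$type == "source"]
  ok_d <- m$channels$detector %in% m$optodes$optode[m$optodes$type == "detector"]
  if (!all(ok_s & ok_d))
    stop("montage channel references an optode not present in the grid")
  invisible(m)
}

#' Channels in a lateral prefrontal strip
#'
#' Convenience accessor used by the simulator defaults: channel ids whose
#' midpoint lies in the leftmost ("L") or rightmost ("R") part of the grid.
#'
#' @param montage A montage from [build_standard_montage()].
#' @param side `"L"` or `"R"`.
#' @return Integer channel ids.
#' @export
lateral_channels <- function(montage = build_standard_montage(), side = c("L", "R")) {
  side <- match.arg(side)
  ch <- montage$channels
  if (side == "L") ch$channel[ch$col_mid <= 1.5] else ch$channel[ch$col_mid >= 4.5]
}
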