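#' A single simulation configuration
#'
#' Positions, species labels and an orthorhombic periodic box.  Coordinates
#' are wrapped into `[0, box)` on construction unless `wrap = FALSE` (keep
#' unwrapped coordinates for displacement analysis).
#'
#' @param positions N x 3 numeric matrix of coordinates (length units).
#' @param box length-3 vector of positive box edge lengths.
#' @param species character vector of N species labels (recycled).
#' @param time frame time (time units).
#' @param wrap wrap coordinates into the box (default TRUE).
#' @return object of class `md_frame`.
#' @export
md_frame <- function(positions, box, species = "A", time = 0, wrap = TRUE) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  stopifnot(ncol(positions) == 3, nrow(positions) >= 2,
            all(is.finite(positions)),
            length(box) == 3, all(box > 0))
  n <- nrow(positions)
  species <- rep_len(as.character(species), n)
  if (wrap) positions <- wrap_positions(positions, box)
  structure(list(positions = positions, box = as.numeric(box),
                 species = species, time = as.numeric(time)),
            class = "md_frame")
}

wrap_positions <- function(positions, box) {
  for (d in 1:3) positions[, d] <- positions[, d] %% box[d]
  positions
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("MD frame: %d atoms (%s), box %.4g x %.4g x %.4g, t = %g\n",
              nrow(x$positions),
              paste(unique(x$species), collapse = ","),
              x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

frame_volume <- function(frame) prod(frame$box)

# pairwise minimum-image distance matrix (used by the R-level analysis code)
min_image_dist <- function(positions, box) {
  n <- nrow(positions)
  dd <- matrix(0, n, n)
  for (d in 1:3) {
    delta <- outer(positions[, d], positions[, d], "-")
    delta <- delta - box[d] * round(delta / box[d])
    dd <- dd + delta^2
  }
  sqrt(dd)
}

# minimum-image displacement vectors from atom i to atoms js
min_image_vec <- function(positions, i, js, box) {
  dv <- positions[js, , drop = FALSE] -
    matrix(positions[i, ], length(js), 3, byrow = TRUE)
  for (d in 1:3) dv[, d] <- dv[, d] - box[d] * round(dv[, d] / box[d])
  dv
}
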