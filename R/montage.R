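#' Schematic 68-channel spherical montage
#'
#' Channel set of a 68-channel Biosemi Active II layout: the 64 standard
#' 10-20/10-10 positions plus a posterior row of PO9, I1, I2 and PO10.
#' Positions are a *schematic* spherical layout generated from the
#' electrode-name grid (one 10% step = 18 degrees; left/right exactly
#' mirror-symmetric), suitable for nearest-neighbour interpolation and
#' ROI geometry; they are not digitized head coordinates.
#'
#' @return a data.frame with columns `channel`, `x` (right), `y` (front),
#'   `z` (up); rows are unit vectors.
#' @examples
#' m <- fpvs_montage()
#' nrow(m)  # 68
#' @export
fpvs_montage <- function() {
  chans <- fpvs_channels()
  pos <- t(vapply(chans, .channel_position, numeric(3)))
  out <- data.frame(channel = chans, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Default 68-channel name set
#'
#' @return character vector of 68 channel names.
#' @export
fpvs_channels <- function() {
  c(
    # Biosemi A1-A32
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
    "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
    "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz",
    # Biosemi B1-B32
    "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8",
    "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6",
    "CP4", "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2",
    # extra posterior row
    "PO9", "I1", "I2", "PO10"
  )
}

# name -> (row, lateral-step) grid; rows: front positive, 18 deg / step
.channel_grid <- function(name) {
  m <- regmatches(name, regexec("^([A-Za-z]+?)(z|[0-9]+)$", name))[[1]]
  if (length(m) != 3) stop("unrecognized channel name: ", name)
  prefix <- m[2]; suffix <- m[3]
  rows <- c(Fp = 4, AF = 3, F = 2, FT = 1, FC = 1, C = 0, T = 0,
            TP = -1, CP = -1, P = -2, PO = -3, O = -4, I = -5)
  if (!prefix %in% names(rows)) stop("unrecognized channel prefix: ", prefix)
  gy <- rows[[prefix]]
  if (suffix == "z") {
    gx <- 0
  } else {
    n <- as.integer(suffix)
    steps <- ceiling(n / 2)
    gx <- if (n %% 2 == 1) -steps else steps  # odd = left
  }
  c(gx = gx, gy = gy)
}

.channel_position <- function(name) {
  g <- .channel_grid(name)
  step <- 18 * pi / 180
  theta <- step * sqrt(g[["gx"]]^2 + g[["gy"]]^2)  # inclination from vertex
  phi <- atan2(g[["gx"]], g[["gy"]])               # azimuth from front midline
  c(x = sin(theta) * sin(phi), y = sin(theta) * cos(phi), z = cos(theta))
}

.montage_positions <- function(montage, channels) {
  idx <- match(channels, montage$channel)
  if (anyNA(idx)) {
    stop("channels missing from montage: ",
         paste(channels[is.na(idx)], collapse = ", "))
  }
  as.matrix(montage[idx, c("x", "y", "z")])
}
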