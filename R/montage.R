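#' Standard 19-channel 10-20 montage
#'
#' Channel labels in the fixed front-to-occipital order used throughout the
#' package. Covariance images and all per-channel tables index channels in
#' this order, so images from different subjects are comparable cell by cell.
#'
#' @return Character vector of 19 channel labels.
#' @export
tova_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "O2")
}

# schematic 2D electrode positions (x: left -1 .. right +1, y: front +1 .. back -1);
# used only by the synthetic generator's smooth spatial kernel
electrode_positions <- function() {
  pos <- rbind(
    Fp1 = c(-0.31, 0.95), Fp2 = c(0.31, 0.95),
    F7 = c(-0.81, 0.59), F3 = c(-0.45, 0.54), Fz = c(0, 0.50),
    F4 = c(0.45, 0.54), F8 = c(0.81, 0.59),
    T3 = c(-1, 0), C3 = c(-0.5, 0), Cz = c(0, 0), C4 = c(0.5, 0), T4 = c(1, 0),
    T5 = c(-0.81, -0.59), P3 = c(-0.45, -0.54), Pz = c(0, -0.50),
    P4 = c(0.45, -0.54), T6 = c(0.81, -0.59),
    O1 = c(-0.31, -0.95), O2 = c(0.31, -0.95)
  )
  colnames(pos) <- c("x", "y")
  pos[tova_montage(), ]
}

#' Default 10-20 nearest-neighbor adjacency map
#'
#' Symmetric neighbor lists for the 19-channel montage, used by
#' [neighbor_average()] to reorganize band power relative to surrounding
#' electrodes. The table follows grid adjacency on the schematic 10-20
#' layout; in particular F3 neighbors Fp1, F7, Fz and C3, so the F3
#' reorganized value is (F3 + Fp1 + F7 + Fz + C3)/5.
#'
#' @return Named list; each element is a character vector of neighbor labels.
#' @export
default_adjacency <- function() {
  adj <- list(
    Fp1 = c("Fp2", "F7", "F3", "Fz"),
    Fp2 = c("Fp1", "Fz", "F4", "F8"),
    F7  = c("Fp1", "F3", "T3"),
    F3  = c("Fp1", "F7", "Fz", "C3"),
    Fz  = c("Fp1", "Fp2", "F3", "F4", "Cz"),
    F4  = c("Fp2", "Fz", "F8", "C4"),
    F8  = c("Fp2", "F4", "T4"),
    T3  = c("F7", "C3", "T5"),
    C3  = c("F3", "T3", "Cz", "P3"),
    Cz  = c("Fz", "C3", "C4", "Pz"),
    C4  = c("F4", "Cz", "T4", "P4"),
    T4  = c("F8", "C4", "T6"),
    T5  = c("T3", "P3", "O1"),
    P3  = c("C3", "T5", "Pz", "O1"),
    Pz  = c("Cz", "P3", "P4", "O1", "O2"),
    P4  = c("C4", "Pz", "T6", "O2"),
    T6  = c("T4", "P4", "O2"),
    O1  = c("T5", "P3", "Pz", "O2"),
    O2  = c("T6", "P4", "Pz", "O1")
  )
  adj
}

# check adjacency symmetry / labels; stops with an informative message
validate_adjacency <- function(adj, labels = tova_montage()) {
  unknown <- setdiff(names(adj), labels)
  if (length(unknown) > 0)
    stop("adjacency map has unknown channel label(s): ",
         paste(unknown, collapse = ", "))
  for (ch in names(adj)) {
    nb <- adj[[ch]]
    bad <- setdiff(nb, labels)
    if (length(bad) > 0)
      stop("adjacency for ", ch, " names unknown channel(s): ",
           paste(bad, collapse = ", "))
    if (ch %in% nb) stop("channel ", ch, " listed as its own neighbor")
    for (other in nb) {
      if (!(ch %in% adj[[other]]))
        stop("adjacency not symmetric: ", ch, " -> ", other,
             " but not ", other, " -> ", ch)
    }
  }
  invisible(adj)
}

#' Frequency bands used throughout the analysis
#'
#' Half-open bands in Hz: delta `[1,4)`, theta `[4,8)`, alpha `[8,12)`,
#' beta `[12,16)`.
#'
#' @return Named list of `c(lo, hi)` pairs.
#' @export
qeeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12), beta = c(12, 16))
}
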