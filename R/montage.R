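#' @useDynLib eegdense, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd var cor quantile rnorm runif qnorm
#' @importFrom utils read.csv write.csv modifyList
NULL

# Scalp geometry is generated, not digitized: electrodes live on a unit
# sphere, placed by the proportional-arc rules of the 10-10 extension of the
# international 10-20 system (10% of the nasion-inion arc = 18 degrees).
# Midline and central-coronal electrodes sit on the two primary arcs; the
# outer ring (polar angle 72 deg) holds 20 equally spaced slots; interior
# rows (F/FC/CP/P and AF/PO) are placed at proportional fractions along the
# planar segment joining the row's midline electrode to its outer-ring
# terminus. The construction is exactly left-right symmetric.

.ring72 <- c(
  Fpz = 90, Fp2 = 72, AF8 = 54, F8 = 36, FT8 = 18, T8 = 0,
  TP8 = -18, PO8 = -54, O2 = -72, Oz = -90, O1 = -108, PO7 = -126,
  P7 = -144, TP7 = -162, T7 = 180, FT7 = 162, F7 = 144, AF7 = 126,
  Fp1 = 108
)

.montage_order <- c(
  "Nz",  "Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8", "F7",
  "F5",  "F3",  "Fz",  "F4",  "F6",  "F8",  "FT7", "FC5", "FC3", "FC1",
  "FCz", "FC2", "FC4", "FC6", "FT8", "T9",  "T7",  "C5",  "C3",  "C1",
  "Cz",  "C2",  "C4",  "C6",  "T8",  "T10", "TP7", "CP5", "CP3", "CP1",
  "CPz", "CP2", "CP4", "CP6", "TP8", "P7",  "P5",  "P3",  "Pz",  "P2",
  "P4",  "P6",  "PO7", "PO3", "POz", "PO4", "PO8", "O1",  "Oz",  "O2"
)

.polar_to_plane <- function(rho_deg, az_deg) {
  r <- rho_deg * pi / 180
  a <- az_deg * pi / 180
  c(r * cos(a), r * sin(a))
}

#' Mirror an electrode label across the scalp midline
#'
#' Left-right homologs in the 10-20 nomenclature swap odd and even numeric
#' suffixes (C3 <-> C4, F7 <-> F8, T9 <-> T10); midline labels (suffix `z`,
#' and `Nz`) map to themselves.
#'
#' @param label character vector of electrode labels.
#' @return character vector of homolog labels.
#' @examples
#' homolog_label(c("C3", "Fz", "T10"))
#' @export
homolog_label <- function(label) {
  vapply(label, function(lb) {
    m <- regmatches(lb, regexpr("[0-9]+$", lb))
    if (length(m) == 0 || m == "") return(lb)
    n <- as.integer(m)
    n2 <- if (n %% 2 == 1) n + 1L else n - 1L
    paste0(sub("[0-9]+$", "", lb), n2)
  }, character(1), USE.NAMES = FALSE)
}

.builtin_planar <- function() {
  p <- matrix(NA_real_, nrow = length(.montage_order), ncol = 2,
              dimnames = list(.montage_order, c("x", "y")))
  set2 <- function(lab, rho, az) p[lab, ] <<- .polar_to_plane(rho, az)

  # primary arcs
  set2("Cz", 0, 0)
  mid_front <- c(Fpz = 72, AFz = 54, Fz = 36, FCz = 18)
  mid_back  <- c(CPz = 18, Pz = 36, POz = 54, Oz = 72)
  for (lb in names(mid_front)) set2(lb, mid_front[[lb]], 90)
  for (lb in names(mid_back))  set2(lb, mid_back[[lb]], -90)
  set2("Nz", 90, 90)
  cor_left  <- c(T9 = 90, T7 = 72, C5 = 54, C3 = 36, C1 = 18)
  cor_right <- c(T10 = 90, T8 = 72, C6 = 54, C4 = 36, C2 = 18)
  for (lb in names(cor_left))  set2(lb, cor_left[[lb]], 180)
  for (lb in names(cor_right)) set2(lb, cor_right[[lb]], 0)
  # outer ring (20 slots at 18 deg; only labels present in the montage)
  for (lb in names(.ring72)) set2(lb, 72, .ring72[[lb]])

  # interior rows: fraction along planar segment midline electrode -> ring
  interp <- function(lab, mid, ring, f) p[lab, ] <<- (1 - f) * p[mid, ] + f * p[ring, ]
  rows <- list(
    list(mid = "Fz",  ring = c("F7", "F8"),
         left = c(F3 = 0.5, F5 = 0.75),  right = c(F4 = 0.5, F6 = 0.75)),
    list(mid = "FCz", ring = c("FT7", "FT8"),
         left = c(FC1 = 0.25, FC3 = 0.5, FC5 = 0.75),
         right = c(FC2 = 0.25, FC4 = 0.5, FC6 = 0.75)),
    list(mid = "CPz", ring = c("TP7", "TP8"),
         left = c(CP1 = 0.25, CP3 = 0.5, CP5 = 0.75),
         right = c(CP2 = 0.25, CP4 = 0.5, CP6 = 0.75)),
    list(mid = "Pz",  ring = c("P7", "P8"),
         left = c(P3 = 0.5, P5 = 0.75),
         right = c(P2 = 0.25, P4 = 0.5, P6 = 0.75)),
    list(mid = "AFz", ring = c("AF7", "AF8"),
         left = c(AF3 = 0.5), right = c(AF4 = 0.5)),
    list(mid = "POz", ring = c("PO7", "PO8"),
         left = c(PO3 = 0.5), right = c(PO4 = 0.5))
  )
  # P8 is absent from the montage; supply the ring slot transiently
  p8 <- .polar_to_plane(72, -36)
  for (rw in rows) {
    for (lb in names(rw$left))  interp(lb, rw$mid, rw$ring[1], rw$left[[lb]])
    for (lb in names(rw$right)) {
      ring_xy <- if (rw$ring[2] %in% rownames(p)) p[rw$ring[2], ] else p8
      p[lb, ] <- (1 - rw$right[[lb]]) * p[rw$mid, ] + rw$right[[lb]] * ring_xy
    }
  }
  p
}

.plane_to_sphere <- function(p2d) {
  r <- sqrt(rowSums(p2d^2))
  a <- atan2(p2d[, 2], p2d[, 1])
  cbind(x = sin(r) * cos(a), y = sin(r) * sin(a), z = cos(r))
}

#' Built-in 60-electrode scalp montage
#'
#' Returns the 60-channel 10-10 montage used throughout the package, in the
#' canonical index order (1 = Nz, 21 = FCz, 31 = Cz, 60 = O2). Positions are
#' unit-sphere coordinates (head modelled as a sphere, vertex Cz at the
#' pole) together with their azimuthal-equidistant planar projection about
#' the vertex, so planar radius is proportional to arc length from Cz and
#' the layout is exactly mirror-symmetric about the midline.
#'
#' @return An object of class `eeg_montage`: a list with `names` (electrode
#'   labels), `pos3d` (n x 3 unit-sphere coordinates), `pos2d` (n x 2 planar
#'   projection, radians of arc).
#' @examples
#' m <- load_builtin_montage()
#' m$names[31]                 # "Cz"
#' m$pos2d["Cz", ]             # origin
#' @export
load_builtin_montage <- function() {
  p2d <- .builtin_planar()
  stopifnot(!anyNA(p2d))
  new_montage(.montage_order, .plane_to_sphere(p2d))
}

#' Construct a montage from labels and 3-D positions
#'
#' @param names character vector of unique electrode labels.
#' @param pos3d numeric matrix, one row per electrode, columns x (right),
#'   y (front), z (up); positions are normalized onto the unit sphere.
#' @return an `eeg_montage` object.
#' @export
new_montage <- function(names, pos3d) {
  pos3d <- as.matrix(pos3d)
  stopifnot(length(names) == nrow(pos3d), ncol(pos3d) == 3,
            !anyDuplicated(names))
  nrm <- sqrt(rowSums(pos3d^2))
  if (any(nrm < 1e-12)) stop("electrode position with zero norm")
  pos3d <- pos3d / nrm
  rownames(pos3d) <- names
  p2d <- project_to_plane(pos3d)
  rownames(p2d) <- names
  structure(list(names = as.character(names), pos3d = pos3d, pos2d = p2d),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d electrodes: %s ... %s\n",
              length(x$names), x$names[1], x$names[length(x$names)]))
  invisible(x)
}

#' Azimuthal-equidistant projection of scalp positions
#'
#' Flattens unit-sphere electrode positions onto the plane tangent at the
#' vertex: planar radius equals the arc distance (polar angle, radians) from
#' the vertex and the azimuth is preserved. The vertex maps to the origin.
#'
#' @param pos3d numeric matrix (n x 3) of positions on or near the unit
#'   sphere.
#' @return n x 2 matrix of planar coordinates (dimensionless, radians).
#' @export
project_to_plane <- function(pos3d) {
  pos3d <- as.matrix(pos3d)
  stopifnot(ncol(pos3d) == 3)
  nrm <- sqrt(rowSums(pos3d^2))
  if (any(nrm < 1e-12)) stop("electrode position with zero norm")
  u <- pos3d / nrm
  rho <- acos(pmin(1, pmax(-1, u[, 3])))
  az <- atan2(u[, 2], u[, 1])
  out <- cbind(x = rho * cos(az), y = rho * sin(az))
  out[rho < 1e-15, ] <- 0  # azimuth undefined at the pole
  rownames(out) <- rownames(pos3d)
  out
}

#' Planar distance between two electrodes
#'
#' Euclidean distance between the montage's projected (planar) electrode
#' positions, the distance measure used by the inverse-distance baseline.
#'
#' @param montage an `eeg_montage`.
#' @param i,j electrode indices (1-based) or labels.
#' @return non-negative scalar distance in planar units (radians of arc).
#' @export
pairwise_distance <- function(montage, i, j) {
  i <- resolve_channel(montage, i)
  j <- resolve_channel(montage, j)
  sqrt(sum((montage$pos2d[i, ] - montage$pos2d[j, ])^2))
}

#' All pairwise planar electrode distances
#'
#' @param montage an `eeg_montage`.
#' @return symmetric n x n matrix of planar distances.
#' @export
montage_distances <- function(montage) {
  d <- as.matrix(stats::dist(montage$pos2d))
  dimnames(d) <- list(montage$names, montage$names)
  d
}

resolve_channel <- function(montage, ch) {
  if (is.character(ch)) {
    idx <- match(ch, montage$names)
    if (anyNA(idx)) stop("unknown electrode label(s): ",
                         paste(ch[is.na(idx)], collapse = ", "))
    return(idx)
  }
  ch <- as.integer(ch)
  if (any(ch < 1 | ch > length(montage$names)))
    stop("electrode index out of range")
  ch
}

#' Partition a montage into observed and target channels
#'
#' @param montage an `eeg_montage`.
#' @param observed electrode labels or indices that are recorded.
#' @param targets electrode labels or indices to reconstruct; defaults to
#'   the complement of `observed`. Must be disjoint from `observed`.
#' @return an object of class `channel_split`: list with integer vectors
#'   `observed` and `targets`, both in montage index order.
#' @export
channel_split <- function(montage, observed, targets = NULL) {
  obs <- sort(unique(resolve_channel(montage, observed)))
  if (length(obs) == 0) stop("observed set must be nonempty")
  tgt <- if (is.null(targets)) setdiff(seq_along(montage$names), obs)
         else sort(unique(resolve_channel(montage, targets)))
  if (length(intersect(obs, tgt)) > 0)
    stop("observed and target sets must be disjoint")
  structure(list(observed = obs, targets = tgt), class = "channel_split")
}

#' @export
print.channel_split <- function(x, ...) {
  cat(sprintf("<channel_split> %d observed / %d target channels\n",
              length(x$observed), length(x$targets)))
  invisible(x)
}

# Default low-density subsets. The four sizes are fixed; the memberships are
# package defaults chosen to be left-right symmetric and to cover frontal,
# central/temporal, parietal and occipital regions. Arbitrary user subsets
# are accepted via channel_split().
.builtin_subsets <- list(
  `9`  = c("Fp1", "Fp2", "F7", "F8", "C3", "Cz", "C4", "O1", "O2"),
  `12` = c("Fp1", "Fp2", "F7", "F8", "Fz", "C3", "Cz", "C4",
           "P3", "P4", "O1", "O2"),
  `15` = c("Fp1", "Fp2", "F7", "F8", "Fz", "T7", "C3", "Cz", "C4", "T8",
           "P3", "Pz", "P4", "O1", "O2"),
  `18` = c("Fp1", "Fp2", "F7", "F8", "Fz", "T7", "C3", "Cz", "C4", "T8",
           "CP3", "CP4", "P3", "Pz", "P4", "O1", "Oz", "O2")
)

#' Built-in symmetric low-density electrode subsets
#'
#' Four whole-scalp, left-right symmetric electrode subsets of 9, 12, 15 and
#' 18 channels used as the low-density "observed" configurations. Every
#' non-midline member has its homolog in the set; the 18-channel subset
#' contains C3, Cz and C4.
#'
#' @param n_observed one of 9, 12, 15, 18.
#' @param montage montage to split; defaults to the built-in 60-channel one.
#' @return a `channel_split`.
#' @examples
#' sp <- builtin_split(18)
#' length(sp$observed); length(sp$targets)
#' @export
builtin_split <- function(n_observed, montage = load_builtin_montage()) {
  key <- as.character(n_observed)
  if (!key %in% names(.builtin_subsets))
    stop("n_observed must be one of 9, 12, 15, 18")
  channel_split(montage, .builtin_subsets[[key]])
}

#' Read / write a montage as JSON
#'
#' The on-disk format is an array of `{label, x, y, z}` records.
#'
#' @param montage an `eeg_montage`.
#' @param path file path.
#' @return `read_montage_json` returns an `eeg_montage`;
#'   `write_montage_json` returns `path` invisibly.
#' @export
write_montage_json <- function(montage, path) {
  df <- data.frame(label = montage$names,
                   x = montage$pos3d[, 1], y = montage$pos3d[, 2],
                   z = montage$pos3d[, 3])
  jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname write_montage_json
#' @export
read_montage_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_montage(df$label, as.matrix(df[, c("x", "y", "z")]))
}
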