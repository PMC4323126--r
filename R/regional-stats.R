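# Regional comparison statistics: AHA sectorization of the mid-ventricular
# annulus, myocardial signal coefficient of variation, MBF spatial
# heterogeneity, septal-lateral and remote-ischaemic differences, and the
# paired t-test used to compare correction strategies. Sample (n-1) standard
# deviations throughout.

#' Coronary territory assignment
#'
#' Standard AHA/ACC mid-ventricular mapping: anterior (1) and anteroseptum
#' (6) to the left anterior descending artery; anterolateral (2) and
#' inferolateral (3) to the circumflex; inferior (4) and inferoseptum (5) to
#' the right coronary artery.
#'
#' @param diseased Character subset of `c("LAD", "LCX", "RCA")` with
#'   significant stenosis; must be nonempty and strict (a remote territory
#'   must exist).
#' @return Object of class `territory_assignment` with the sector->territory
#'   map and the diseased set.
#' @export
territory_assignment <- function(diseased) {
  territories <- c("LAD", "LCX", "RCA")
  diseased <- unique(as.character(diseased))
  if (!all(diseased %in% territories)) stop("unknown territory in diseased set")
  if (length(diseased) == 0L) stop("diseased set must be nonempty")
  if (length(diseased) == length(territories))
    stop("no remote territory: all three territories diseased")
  structure(list(
    sector_territory = c(anterior = "LAD", anterolateral = "LCX",
                         inferolateral = "LCX", inferior = "RCA",
                         inferoseptum = "RCA", anteroseptum = "LAD"),
    diseased = diseased), class = "territory_assignment")
}

# Display angle of pixels about a centre: degrees clockwise from vertical
# (anterior-up) in the standard short-axis display, image rows increasing
# downward.
display_angle_deg <- function(y, x, center) {
  (atan2(x - center[2], -(y - center[1])) * 180 / pi) %% 360
}

#' Assign myocardial pixels to six AHA sectors
#'
#' Each myocardial pixel is labelled by its polar angle about the cavity
#' centre into six 60-degree sectors starting at the anterior RV insertion
#' angle, in clockwise order anterior, anterolateral, inferolateral,
#' inferior, inferoseptum, anteroseptum.
#'
#' @param myo_mask Annular myocardial [roi_mask()].
#' @param center `(y, x)` cavity centre, inside the annulus.
#' @param rv_insertion_angle_deg Anterior RV insertion angle, degrees
#'   clockwise from vertical in the anterior-up display.
#' @return A [segment_labels()]; errors if any sector is empty.
#' @export
sectorize <- function(myo_mask, center, rv_insertion_angle_deg) {
  idx <- which(myo_mask$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty myocardial mask")
  ang <- display_angle_deg(idx[, 1], idx[, 2], center)
  sec <- (floor(((ang - rv_insertion_angle_deg) %% 360) / 60) %% 6) + 1
  labels <- matrix(NA_integer_, nrow(myo_mask$mask), ncol(myo_mask$mask))
  labels[myo_mask$mask] <- as.integer(sec)
  counts <- tabulate(sec, 6)
  if (any(counts == 0L))
    stop("empty sector(s): ", paste(SECTOR_NAMES[counts == 0L], collapse = ", "))
  segment_labels(labels, rv_insertion_angle_deg)
}

#' Coefficient of variation of myocardial signal intensity
#'
#' `100 * sample SD / mean` of the image over the mask, in percent.
#'
#' @param image 2D frame.
#' @param myo_mask Myocardial [roi_mask()] (>= 2 pixels).
#' @return Percent CoV.
#' @export
cov_si <- function(image, myo_mask) {
  check_mask_shape(myo_mask, dim(image), "myocardial mask")
  v <- image[myo_mask$mask]
  if (length(v) < 2L) stop("need at least 2 myocardial pixels")
  if (mean(v) <= 0) stop("non-positive mean signal")
  100 * sd(v) / mean(v)
}

#' Spatial heterogeneity of a pixel-wise MBF map
#'
#' Sample standard deviation of pixel-wise MBF divided by mean pixel MBF,
#' in percent, over converged myocardial pixels.
#'
#' @param map An `mbf_map_result`.
#' @param myo_mask Optional mask restricting the evaluated region; defaults
#'   to the map's own mask.
#' @return Percent heterogeneity.
#' @export
heterogeneity <- function(map, myo_mask = map$mask) {
  sel <- myo_mask$mask & map$mask$mask & !is.na(map$converged) & map$converged
  v <- map$mbf[sel]
  if (length(v) < 2L) stop("need at least 2 converged pixels")
  if (mean(v) <= 0) stop("non-positive mean MBF")
  100 * sd(v) / mean(v)
}

#' Per-sector mean MBF
#'
#' Mean of converged pixel MBF in each of the six sectors.
#'
#' @param map An `mbf_map_result`.
#' @param labels A [segment_labels()] covering the map's mask.
#' @return Named numeric vector of six sector means.
#' @export
sector_stats <- function(map, labels) {
  if (!identical(dim(labels$labels), dim(map$mbf)))
    stop("labels shape does not match map")
  ok <- map$mask$mask & !is.na(map$converged) & map$converged
  means <- vapply(1:6, function(s) {
    sel <- ok & !is.na(labels$labels) & labels$labels == s
    if (!any(sel)) stop("sector ", SECTOR_NAMES[s], " has no converged pixels")
    mean(map$mbf[sel])
  }, numeric(1))
  setNames(means, SECTOR_NAMES)
}

#' Septal minus lateral wall MBF
#'
#' Mean of the two septal sector means minus mean of the two lateral sector
#' means.
#'
#' @param sector_means Named six-sector means from [sector_stats()].
#' @return Difference in the map's flow units.
#' @export
septal_lateral_difference <- function(sector_means) {
  mean(sector_means[c("anteroseptum", "inferoseptum")]) -
    mean(sector_means[c("anterolateral", "inferolateral")])
}

#' Remote and ischaemic territory MBF and their difference
#'
#' Territory means are unweighted means of their sector means; the ischaemic
#' mean pools the sectors of diseased territories, the remote mean the rest.
#'
#' @param sector_means Named six-sector means from [sector_stats()].
#' @param assignment A [territory_assignment()].
#' @return `list(remote, ischaemic, difference)` with
#'   `difference = remote - ischaemic`.
#' @export
remote_ischaemic_difference <- function(sector_means, assignment) {
  if (!inherits(assignment, "territory_assignment"))
    stop("assignment must be a territory_assignment")
  terr <- assignment$sector_territory[names(sector_means)]
  isch <- mean(sector_means[terr %in% assignment$diseased])
  remote <- mean(sector_means[!terr %in% assignment$diseased])
  list(remote = remote, ischaemic = isch, difference = remote - isch)
}

#' Paired t-test (closed form)
#'
#' Classical paired t-test on `d = x - y`: `t = mean(d) / (sd(d) / sqrt(n))`,
#' `df = n - 1`, two-sided p from the t distribution.
#'
#' @param x,y Paired samples of equal length `n >= 2`.
#' @return `list(t, df, p)`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  d <- x - y
  s <- sd(d)
  if (s == 0) stop("degenerate pairs: zero variance of differences")
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1L, p = 2 * pt(-abs(t), n - 1L))
}
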