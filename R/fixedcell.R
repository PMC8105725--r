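auto_threshold <- function(img) {
  rng <- range(img, finite = TRUE)
  if (!(diff(rng) > 0)) return(Inf)
  x <- (img - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  rng[1] + th * diff(rng)
}

label_features <- function(labels, pixel_size_um) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0)
  if (!length(ids)) {
    return(tibble::tibble(
      cell_id = integer(), area_px = numeric(), radius_um = numeric(),
      x_um = numeric(), y_um = numeric(), ecc_ratio = numeric()))
  }
  mom <- EBImage::computeFeatures.moment(labels)
  mom <- mom[ids, , drop = FALSE]
  area <- tabulate(as.vector(labels), nbins = max(ids))[ids]
  # EBImage treats dim 1 as x; our matrices are [row = y, col = x], so
  # m.cx indexes rows (y) and m.cy indexes columns (x)
  ecc <- mom[, "m.eccentricity"]
  tibble::tibble(
    cell_id = as.integer(ids),
    area_px = as.numeric(area),
    radius_um = sqrt(area / pi) * pixel_size_um,
    x_um = (mom[, "m.cy"] - 0.5) * pixel_size_um,
    y_um = (mom[, "m.cx"] - 0.5) * pixel_size_um,
    ecc_ratio = 1 / sqrt(pmax(1 - ecc^2, .Machine$double.eps)))
}

#' Segment nuclei and cytoplasm in a fixed-cell field
#'
#' Nuclei are found by thresholding the DAPI channel (Otsu by default) and
#' splitting touching objects with a watershed on the distance map; cell
#' bodies are then grown from the nucleus seeds over the thresholded cell
#' marker channel (GFP or phalloidin) by marker-controlled propagation.
#' The cytoplasm of a cell is its body minus its nucleus.
#'
#' Inputs should be illumination-corrected, background-subtracted images
#' (see [preprocess_fixed()]).
#'
#' @param dapi DAPI channel matrix.
#' @param marker cell-body marker channel matrix.
#' @param pixel_size_um pixel size, micrometres.
#' @param dapi_threshold,marker_threshold absolute thresholds; `NULL`
#'   (default) uses Otsu.
#' @param min_nucleus_px discard nucleus objects smaller than this many
#'   pixels (specks; default 9).
#' @return An object of class `cell_segmentation`: list with `cells` (a
#'   tibble of per-cell shape descriptors: nucleus and cytoplasm
#'   equivalent-circle radii in micrometres, ellipse axis ratios,
#'   centroids, neighbour counts within 16 um — including the cell itself
#'   — and border contact), `nucleus_labels`, `cell_labels`,
#'   `pixel_size_um`. An empty field yields an empty `cells` tibble.
#' @export
segment_cells <- function(dapi, marker, pixel_size_um,
                          dapi_threshold = NULL, marker_threshold = NULL,
                          min_nucleus_px = 9) {
  stopifnot(is.matrix(dapi), is.matrix(marker),
            all(dim(dapi) == dim(marker)), pixel_size_um > 0)
  th_d <- dapi_threshold %||% auto_threshold(dapi)
  th_m <- marker_threshold %||% auto_threshold(marker)
  empty <- structure(
    list(cells = tibble::tibble(), nucleus_labels = matrix(0L, nrow(dapi),
         ncol(dapi)), cell_labels = matrix(0L, nrow(dapi), ncol(dapi)),
         pixel_size_um = pixel_size_um),
    class = "cell_segmentation")

  nmask <- dapi > th_d
  if (!any(nmask)) return(empty)
  nlab_img <- EBImage::watershed(EBImage::distmap(nmask))
  nlab <- matrix(as.integer(EBImage::imageData(nlab_img)),
                 nrow(dapi), ncol(dapi))
  # drop specks and relabel contiguously
  areas <- tabulate(as.vector(nlab))
  keep <- which(areas >= min_nucleus_px)
  if (!length(keep)) return(empty)
  relab <- integer(max(nlab))
  relab[keep] <- seq_along(keep)
  nlab[nlab > 0] <- relab[nlab[nlab > 0]]
  if (!any(nlab > 0)) return(empty)

  cmask <- (marker > th_m) | (nlab > 0)
  clab_img <- EBImage::propagate(EBImage::Image(marker),
                                 EBImage::Image(nlab), mask = cmask)
  clab <- matrix(as.integer(EBImage::imageData(clab_img)),
                 nrow(dapi), ncol(dapi))
  cytolab <- clab
  cytolab[nlab > 0] <- 0L

  nf <- label_features(nlab, pixel_size_um)
  cf <- label_features(cytolab, pixel_size_um)
  cells <- dplyr::left_join(
    dplyr::rename(nf, nucleus_area_px = "area_px",
                  nucleus_radius_um = "radius_um",
                  nucleus_ecc = "ecc_ratio"),
    dplyr::select(
      dplyr::rename(cf, cyto_area_px = "area_px",
                    cyto_radius_um = "radius_um", cyto_ecc = "ecc_ratio"),
      "cell_id", "cyto_area_px", "cyto_radius_um", "cyto_ecc"),
    by = "cell_id")

  # border contact of the full cell body
  H <- nrow(clab); W <- ncol(clab)
  border_ids <- unique(c(clab[1, ], clab[H, ], clab[, 1], clab[, W]))
  cells$touches_border <- cells$cell_id %in% setdiff(border_ids, 0)

  # neighbour count within 16 um of the nuclear centroid (self included)
  d <- as.matrix(stats::dist(cbind(cells$x_um, cells$y_um)))
  cells$n_neighbors_16um <- as.integer(rowSums(d <= 16))

  structure(
    list(cells = cells, nucleus_labels = nlab, cell_labels = clab,
         pixel_size_um = pixel_size_um),
    class = "cell_segmentation")
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat(sprintf("<cell_segmentation> %d cell(s), %g um/px\n",
              nrow(x$cells), x$pixel_size_um))
  invisible(x)
}

#' Morphological quality filters for segmented cells
#'
#' Applies the standard debris/aggregate screens and records each rule's
#' outcome per cell: nucleus equivalent-circle radius within
#' `nucleus_radius_um` (default 5.5-10 um, inclusive), cytoplasm radius
#' strictly below `cyto_radius_max_um` (default 15 um), nucleus and
#' cytoplasm ellipse axis ratios at most `nucleus_ecc_max` (1.66) and
#' `cyto_ecc_max` (2.25), at most `max_neighbors` (5) segmented nuclei
#' within 16 um of the nuclear centroid (the cell itself included), and no
#' contact between the cell body and the image border. Any rule can be
#' disabled by passing `NULL`; `pass_filters` is the conjunction of the
#' enabled rules.
#'
#' @param seg a [segment_cells()] result.
#' @param nucleus_radius_um length-2 inclusive range, or `NULL`.
#' @param cyto_radius_max_um strict upper bound, or `NULL`.
#' @param nucleus_ecc_max,cyto_ecc_max axis-ratio bounds, or `NULL`.
#' @param max_neighbors crowding bound, or `NULL`.
#' @param exclude_border logical; `FALSE` disables the border rule.
#' @return `seg` with per-rule logical columns and `pass_filters` added to
#'   `seg$cells`.
#' @export
apply_cell_filters <- function(seg,
                               nucleus_radius_um = c(5.5, 10),
                               cyto_radius_max_um = 15,
                               nucleus_ecc_max = 1.66,
                               cyto_ecc_max = 2.25,
                               max_neighbors = 5,
                               exclude_border = TRUE) {
  stopifnot(inherits(seg, "cell_segmentation"))
  cells <- seg$cells
  if (!nrow(cells)) return(seg)
  on_or <- function(x) if (is.null(x)) rep(TRUE, nrow(cells)) else x
  cells$pass_nucleus_size <- on_or(
    if (!is.null(nucleus_radius_um))
      cells$nucleus_radius_um >= nucleus_radius_um[1] &
      cells$nucleus_radius_um <= nucleus_radius_um[2])
  cells$pass_cyto_size <- on_or(
    if (!is.null(cyto_radius_max_um))
      !is.na(cells$cyto_radius_um) &
      cells$cyto_radius_um < cyto_radius_max_um)
  cells$pass_nucleus_ecc <- on_or(
    if (!is.null(nucleus_ecc_max)) cells$nucleus_ecc <= nucleus_ecc_max)
  cells$pass_cyto_ecc <- on_or(
    if (!is.null(cyto_ecc_max))
      !is.na(cells$cyto_ecc) & cells$cyto_ecc <= cyto_ecc_max)
  cells$pass_crowding <- on_or(
    if (!is.null(max_neighbors)) cells$n_neighbors_16um <= max_neighbors)
  cells$pass_border <- on_or(
    if (isTRUE(exclude_border)) !cells$touches_border)
  cells$pass_filters <- cells$pass_nucleus_size & cells$pass_cyto_size &
    cells$pass_nucleus_ecc & cells$pass_cyto_ecc & cells$pass_crowding &
    cells$pass_border
  seg$cells <- cells
  seg
}

#' Measure nuclear and cytoplasmic staining per cell
#'
#' Extracts the mean stain intensity over each cell's nucleus and
#' cytoplasm masks and, in `"ratio"` mode, their quotient — the nuclear
#' translocation readout. Cells with an empty or non-positive cytoplasm
#' signal get a missing ratio.
#'
#' @param seg a [segment_cells()] result (filter columns, if present, are
#'   carried through).
#' @param stain corrected stain-channel matrix.
#' @param mode `"ratio"` (nuclear / cytoplasmic, e.g. RelA translocation)
#'   or `"nuclear"` (nuclear mean only, e.g. phospho-p38).
#' @return A tibble with `cell_id`, `nuclear_mean`, `cyto_mean`, `ratio`
#'   (in `"ratio"` mode) and `pass_filters` when available.
#' @export
measure_stain <- function(seg, stain, mode = c("ratio", "nuclear")) {
  mode <- match.arg(mode)
  stopifnot(inherits(seg, "cell_segmentation"), is.matrix(stain),
            all(dim(stain) == dim(seg$nucleus_labels)))
  cells <- seg$cells
  if (!nrow(cells)) return(tibble::tibble())
  nlab <- seg$nucleus_labels
  cytolab <- seg$cell_labels
  cytolab[nlab > 0] <- 0L
  mean_by_label <- function(lab) {
    v <- as.vector(stain)[lab > 0]
    l <- lab[lab > 0]
    s <- tapply(v, l, mean)
    out <- rep(NA_real_, nrow(cells))
    out[match(as.integer(names(s)), cells$cell_id)] <- as.numeric(s)
    out
  }
  res <- tibble::tibble(
    cell_id = cells$cell_id,
    nuclear_mean = mean_by_label(nlab),
    cyto_mean = mean_by_label(cytolab))
  if (mode == "ratio") {
    res$ratio <- ifelse(!is.na(res$cyto_mean) & res$cyto_mean > 0,
                        res$nuclear_mean / res$cyto_mean, NA_real_)
  }
  if ("pass_filters" %in% names(cells))
    res$pass_filters <- cells$pass_filters
  res
}

#' Normalize staining values to the unstimulated population
#'
#' Divides each value by the median of the unstimulated cells' values (the
#' day's baseline), making staining intensities comparable across
#' replicates and days.
#'
#' @param values numeric vector of per-cell staining values.
#' @param unstimulated_values values of the unstimulated cells (>= 1).
#' @return `values / median(unstimulated_values)`.
#' @export
normalize_to_unstimulated <- function(values, unstimulated_values) {
  if (!length(unstimulated_values))
    stop("need at least one unstimulated value")
  m <- median(unstimulated_values)
  if (m <= 0) stop("median of unstimulated values must be positive")
  values / m
}

#' Maximum projection of selected planes
#'
#' Optional pre-step for confocal stacks: pixelwise maximum over the given
#' plane indices.
#'
#' @param stack `H x W x Z` array.
#' @param planes plane indices to project (default: all).
#' @return A matrix.
#' @export
max_project <- function(stack, planes = NULL) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  planes <- planes %||% seq_len(dim(stack)[3])
  apply(stack[, , planes, drop = FALSE], c(1, 2), max)
}

#' Compare replicate means between two conditions
#'
#' Convenience unpaired two-tailed Student's t test on replicate means
#' (e.g. stimulated wild type vs stimulated knockout wells).
#'
#' @param x,y numeric vectors of replicate means.
#' @return A one-row tibble: `estimate_x`, `estimate_y`, `t`, `df`,
#'   `p_value`.
#' @export
compare_conditions <- function(x, y) {
  ht <- t.test(x, y, var.equal = TRUE)
  tibble::tibble(
    estimate_x = mean(x), estimate_y = mean(y),
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
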