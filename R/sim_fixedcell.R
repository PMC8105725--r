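#' Simulate a fixed-cell immunofluorescence field with known ground truth
#'
#' Renders a wide-field (20x-style) three-channel image of cells modelled as
#' disk nuclei inside larger cytoplasm disks: a DAPI channel (nuclei), a cell
#' marker channel (whole cell body, e.g. GFP or phalloidin) and an antibody
#' stain channel whose nuclear : cytoplasmic mean-intensity ratio is
#' `nuclear_ratio`. Optional constructions exercise the downstream
#' morphological filters: a tight 6-cell cluster (crowding violation), cells
#' whose bodies touch the image border, and elongated DAPI-bright debris
#' (eccentricity violation).
#'
#' Nuclei are never allowed to overlap; configurations that cannot be placed
#' without overlap (or without room at the requested density) are refused.
#'
#' @param n_cells number of well-separated, filter-passing cells.
#' @param nuclear_ratio nuclear : cytoplasmic mean stain ratio (> 0).
#' @param pixel_size_um pixel size, micrometres (default 0.283, a 20x camera
#'   pixel).
#' @param image_shape `c(H, W)` pixels.
#' @param nucleus_radius_um,cyto_radius_um disk radii of normal cells.
#' @param stain_cyto_level cytoplasmic stain level, ADU.
#' @param dapi_level,marker_level channel foreground levels, ADU.
#' @param n_crowded if `> 0`, adds one cluster of 6 small cells whose
#'   nuclear centroids all lie within 16 um of each other's.
#' @param n_edge number of border-touching cells.
#' @param n_debris number of elongated debris objects (axis ratio 2).
#' @param noise_sd Gaussian noise SD added per channel, ADU.
#' @param seed seed.
#'
#' @return List with `dapi`, `marker`, `stain` (numeric matrices),
#'   `pixel_size_um`, and `truth` (tibble: `cell_id`, `x_um`, `y_um`,
#'   `nucleus_r_um`, `cyto_r_um`, `type`, `expected_pass`).
#' @export
simulate_fixedcell_field <- function(n_cells = 8,
                                     nuclear_ratio = 1,
                                     pixel_size_um = 0.283,
                                     image_shape = c(360, 360),
                                     nucleus_radius_um = 7,
                                     cyto_radius_um = 12,
                                     stain_cyto_level = 100,
                                     dapi_level = 500,
                                     marker_level = 300,
                                     n_crowded = 0,
                                     n_edge = 0,
                                     n_debris = 0,
                                     noise_sd = 0,
                                     seed = 1L) {
  stopifnot(nuclear_ratio > 0, n_cells >= 0)
  H <- image_shape[1]; W <- image_shape[2]; px <- pixel_size_um

  cells <- tibble::tibble(
    x = numeric(), y = numeric(), nr = numeric(), cr = numeric(),
    type = character(), theta = numeric(), axis_ratio = numeric())
  add_cell <- function(cells, x, y, nr, cr, type,
                       theta = 0, axis_ratio = 1) {
    dplyr::bind_rows(cells, tibble::tibble(
      x = x, y = y, nr = nr, cr = cr, type = type,
      theta = theta, axis_ratio = axis_ratio))
  }
  # place a centre at least `clear` um from all existing cytoplasm disks
  place <- function(cells, clear_r, xmin, xmax, ymin, ymax) {
    for (a in seq_len(400L)) {
      x <- runif(1, xmin, xmax); y <- runif(1, ymin, ymax)
      if (!nrow(cells) ||
          all(sqrt((cells$x - x)^2 + (cells$y - y)^2) >
              cells$cr + clear_r + 1)) return(c(x, y))
    }
    stop("could not place cells at the requested density (packing limit)")
  }

  withr::with_seed(seed, {
    margin <- cyto_radius_um + 2 * px
    for (i in seq_len(n_cells)) {
      p <- place(cells, cyto_radius_um, margin, W * px - margin,
                 margin, H * px - margin)
      cells <- add_cell(cells, p[1], p[2], nucleus_radius_um,
                        cyto_radius_um, "normal")
    }
    if (n_crowded > 0) {
      # 6 small cells: one centre + 5 on an 8.2 um ring. Nuclei of radius
      # 4 um never overlap (nearest spacing 8.2 um centre-ring, 9.6 um on
      # the ring) yet every pair of nuclear centroids is within 16 um
      # (largest chord 15.6 um), so all six violate crowding
      ring <- 8.2; nr <- 4; cr <- 5.5
      clear <- ring + cr
      p <- place(cells, clear, clear + margin, W * px - clear - margin,
                 clear + margin, H * px - clear - margin)
      cells <- add_cell(cells, p[1], p[2], nr, cr, "crowded")
      for (k in seq_len(5L)) {
        ang <- 2 * pi * k / 5
        cells <- add_cell(cells, p[1] + ring * cos(ang),
                          p[2] + ring * sin(ang), nr, cr, "crowded")
      }
    }
    for (i in seq_len(n_edge)) {
      # nucleus fully inside, cell body crossing the border
      side <- sample(4L, 1L)
      off <- nucleus_radius_um + 2
      along <- runif(1, margin, (if (side <= 2) W else H) * px - margin)
      p <- switch(side,
                  c(along, off), c(along, H * px - off),
                  c(off, along), c(W * px - off, along))
      if (nrow(cells) &&
          any(sqrt((cells$x - p[1])^2 + (cells$y - p[2])^2) <=
              cells$cr + cyto_radius_um + 1)) next
      cells <- add_cell(cells, p[1], p[2], nucleus_radius_um,
                        cyto_radius_um, "edge")
    }
    for (i in seq_len(n_debris)) {
      # elongated object: nuclear axis ratio 2 (> 1.66), area-equivalent
      # radius inside the size window so only eccentricity fails
      a <- 9; b <- 4.5
      p <- place(cells, a + 2, margin, W * px - margin,
                 margin, H * px - margin)
      cells <- add_cell(cells, p[1], p[2], sqrt(a * b), sqrt(a * b) + 2,
                        "elongated", theta = runif(1, 0, pi),
                        axis_ratio = 2)
    }

    # refuse overlapping nuclei
    if (nrow(cells) > 1) {
      d <- as.matrix(stats::dist(cbind(cells$x, cells$y)))
      lim <- outer(cells$nr, cells$nr, `+`)
      diag(d) <- Inf
      if (any(d < lim))
        stop("overlapping nuclei: configuration refused (packing limit)")
    }

    xs <- ((seq_len(W) - 0.5) * px)
    ys <- ((seq_len(H) - 0.5) * px)
    X <- matrix(xs, H, W, byrow = TRUE)
    Y <- matrix(ys, H, W)
    dapi <- matrix(0, H, W); marker <- matrix(0, H, W)
    stain <- matrix(0, H, W)
    for (i in seq_len(nrow(cells))) {
      ci <- cells[i, ]
      dx <- X - ci$x; dy <- Y - ci$y
      if (ci$axis_ratio > 1) {
        u <- dx * cos(ci$theta) + dy * sin(ci$theta)
        v <- -dx * sin(ci$theta) + dy * cos(ci$theta)
        aa <- ci$nr * sqrt(ci$axis_ratio); bb <- ci$nr / sqrt(ci$axis_ratio)
        nuc <- (u / aa)^2 + (v / bb)^2 <= 1
        aa2 <- ci$cr * sqrt(ci$axis_ratio); bb2 <- ci$cr / sqrt(ci$axis_ratio)
        cell <- (u / aa2)^2 + (v / bb2)^2 <= 1
      } else {
        r2 <- dx^2 + dy^2
        nuc <- r2 <= ci$nr^2
        cell <- r2 <= ci$cr^2
      }
      dapi[nuc] <- dapi_level
      marker[cell] <- marker_level
      stain[cell & !nuc] <- stain_cyto_level
      stain[nuc] <- stain_cyto_level * nuclear_ratio
    }
    if (noise_sd > 0) {
      dapi <- dapi + matrix(rnorm(H * W, 0, noise_sd), H, W)
      marker <- marker + matrix(rnorm(H * W, 0, noise_sd), H, W)
      stain <- stain + matrix(rnorm(H * W, 0, noise_sd), H, W)
    }
  })

  truth <- tibble::tibble(
    cell_id = seq_len(nrow(cells)), x_um = cells$x, y_um = cells$y,
    nucleus_r_um = cells$nr, cyto_r_um = cells$cr, type = cells$type,
    expected_pass = cells$type == "normal")
  list(dapi = dapi, marker = marker, stain = stain,
       pixel_size_um = px, truth = truth)
}
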