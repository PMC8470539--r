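#' Colour-class definition for image discretisation
#'
#' Maps grid-cell mean colours to discrete states.  The default follows the
#' four-class setup used for multiplexed fluorescence images of cell
#' populations: state 0 black (background / microenvironment), 1 green,
#' 2 red, 3 blue.  A cell whose mean brightness falls below
#' `black_threshold` is background; otherwise it takes the state of the
#' nearest reference colour in RGB distance.
#'
#' @param labels character vector of class labels.
#' @param reference numeric matrix (one row per class, columns R,G,B in
#'   \[0, 1\]).
#' @param black_threshold brightness cut for the background guard
#'   (default 40/255).
#' @param background label treated as background (default the first).
#' @return an object of class `color_class_def`.
#' @export
color_classes <- function(labels = c("black", "green", "red", "blue"),
                          reference = rbind(c(0, 0, 0), c(0, 1, 0),
                                            c(1, 0, 0), c(0, 0, 1)),
                          black_threshold = 40 / 255,
                          background = labels[1L]) {
  reference <- as.matrix(reference)
  stopifnot(length(labels) == nrow(reference), ncol(reference) == 3L,
            background %in% labels)
  structure(list(labels = labels, reference = reference,
                 n_states = length(labels),
                 black_threshold = black_threshold,
                 background_state = match(background, labels) - 1L),
            class = "color_class_def")
}

load_rgb_image <- function(image) {
  if (is.character(image)) {
    if (grepl("\\.png$", image, ignore.case = TRUE)) {
      if (!requireNamespace("png", quietly = TRUE)) stop("png package required")
      image <- png::readPNG(image)
    } else if (grepl("\\.tiff?$", image, ignore.case = TRUE)) {
      if (!requireNamespace("tiff", quietly = TRUE)) stop("tiff package required")
      image <- tiff::readTIFF(image)
    } else stop("unsupported image format (PNG or TIFF expected)")
  }
  if (length(dim(image)) == 2L) image <- array(rep(image, 3L), c(dim(image), 3L))
  if (dim(image)[3L] > 3L) image <- image[, , 1:3, drop = FALSE]
  image
}

#' Discretise an RGB image into a state grid
#'
#' Partitions the image into a `grid_shape` grid of cells, averages the RGB
#' of the pixels inside each cell, and assigns every cell a state by the
#' colour-class rule (background brightness guard, then nearest reference
#' colour).  Deterministic.
#'
#' @param image an RGB array (H x W x 3, values in \[0, 1\]) or a PNG/TIFF
#'   file path.
#' @param grid_shape `c(rows, cols)` of the cell grid; the image must be at
#'   least that large in pixels.
#' @param colors a [color_classes()] definition.
#' @return an object of class `state_grid`: `states` (rows x cols integer
#'   matrix), `topology` (open-boundary lattice; an image has borders),
#'   `colors`, `provenance`.
#' @export
discretize_image <- function(image, grid_shape, colors = color_classes()) {
  img <- load_rgb_image(image)
  H <- dim(img)[1L]; W <- dim(img)[2L]
  R <- grid_shape[1L]; C <- grid_shape[2L]
  if (H < R || W < C) stop("grid (", R, "x", C, ") larger than image (",
                           H, "x", W, " pixels)")
  rb <- floor(seq(0L, H, length.out = R + 1L))
  cb <- floor(seq(0L, W, length.out = C + 1L))
  states <- matrix(0L, R, C)
  for (i in seq_len(R)) for (j in seq_len(C)) {
    px <- img[(rb[i] + 1L):rb[i + 1L], (cb[j] + 1L):cb[j + 1L], , drop = FALSE]
    m <- c(mean(px[, , 1L]), mean(px[, , 2L]), mean(px[, , 3L]))
    if (mean(m) < colors$black_threshold) {
      states[i, j] <- colors$background_state
    } else {
      d2 <- rowSums(sweep(colors$reference, 2L, m, "-")^2)
      states[i, j] <- which.min(d2) - 1L
    }
  }
  structure(list(states = states,
                 topology = lattice_topology(c(R, C), periodic = FALSE),
                 colors = colors,
                 provenance = list(grid_shape = c(R, C),
                                   image_size = c(H, W))),
            class = "state_grid")
}

#' Render a state grid as an RGB image
#'
#' Each cell becomes a `cell_px` x `cell_px` block of its reference colour,
#' optionally perturbed by additive Gaussian noise (clipped to \[0, 1\]).
#' At zero noise, [discretize_image()] of the rendering recovers the grid
#' exactly.
#'
#' @param grid a `state_grid`, or an integer state matrix.
#' @param colors a [color_classes()] (taken from the grid if present).
#' @param cell_px pixels per cell side (default 4).
#' @param noise_sd additive RGB noise standard deviation (default 0).
#' @param seed optional RNG seed for the noise.
#' @return an H x W x 3 array in \[0, 1\].
#' @export
render_state_grid <- function(grid, colors = NULL, cell_px = 4L,
                              noise_sd = 0, seed = NULL) {
  if (inherits(grid, "state_grid")) {
    if (is.null(colors)) colors <- grid$colors
    grid <- grid$states
  }
  if (is.null(colors)) colors <- color_classes()
  if (!is.null(seed)) set.seed(seed)
  R <- nrow(grid); C <- ncol(grid)
  img <- array(0, c(R * cell_px, C * cell_px, 3L))
  for (ch in 1:3) {
    chan <- matrix(colors$reference[grid + 1L, ch], R, C)
    img[, , ch] <- chan[rep(seq_len(R), each = cell_px),
                        rep(seq_len(C), each = cell_px)]
  }
  if (noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, noise_sd)
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  img
}

#' Generate a synthetic labelled-tissue image with known ground truth
#'
#' Draws a ground-truth state grid from a known Potts model (fields set from
#' the requested per-class densities, couplings as given) and renders it as
#' an RGB image with additive noise.  A stand-in for real multiplexed
#' fluorescence images: both the image and the exact ground truth are
#' returned, so discretisation and missing-state inference can be scored
#' against the truth.
#'
#' @param grid_shape `c(rows, cols)` of the cell grid.
#' @param densities target per-class densities (length Q, sum 1).
#' @param couplings Q x Q symmetric coupling matrix (negative entries are
#'   attractive, e.g. a negative blue-blue coupling clusters blue cells);
#'   default 0 (independent cells).
#' @param colors a [color_classes()] with Q classes.
#' @param coupling_scale multiplier applied to `couplings` (the extensive
#'   energy scale: order-1 couplings produce visible clustering).
#' @param field_compensation subtract the first-order mean-field shift
#'   `mean(degree) * couplings %*% densities` from the fields (default), so
#'   the realised class densities stay near the nominal ones even with
#'   sizeable couplings; without it attractive couplings inflate their
#'   class's density.
#' @param cell_px,noise_sd rendering options, see [render_state_grid()].
#' @param n_samples,burn_in Metropolis settings for the ground-truth draw.
#' @param seed optional RNG seed.
#' @return list with `image`, `grid` (ground-truth `state_grid`), `params`
#'   (the generating `potts_parameters`).
#' @export
generate_synthetic_tissue <- function(grid_shape = c(20L, 20L),
                                      densities = c(0.4, 0.25, 0.2, 0.15),
                                      couplings = NULL,
                                      colors = color_classes(),
                                      coupling_scale = 1,
                                      field_compensation = TRUE,
                                      cell_px = 4L, noise_sd = 0,
                                      n_samples = 1L, burn_in = 2000L,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- length(densities)
  stopifnot(Q == colors$n_states, abs(sum(densities) - 1) < 1e-8)
  if (is.null(couplings)) couplings <- matrix(0, Q, Q)
  topo <- lattice_topology(grid_shape, periodic = FALSE)
  J <- coupling_scale * couplings
  h <- -log(pmax(densities, 1e-12))
  if (field_compensation)
    h <- h - mean(node_degree(topo)) * as.numeric(J %*% densities)
  params <- potts_parameters(h, list(spatial = J), Q)
  ens <- sample_potts(params, topo, n_samples = n_samples, burn_in = burn_in,
                      stride = 1L)
  states <- matrix(ens$states[nrow(ens$states), ], grid_shape[1L],
                   grid_shape[2L], byrow = TRUE)
  grid <- structure(list(states = states, topology = topo, colors = colors,
                         provenance = list(synthetic = TRUE,
                                           densities = densities)),
                    class = "state_grid")
  list(image = render_state_grid(grid, colors, cell_px = cell_px,
                                 noise_sd = noise_sd),
       grid = grid, params = params)
}

#' Infer the positions of hidden states by clamped sampling
#'
#' Mirrors the missing-marker protocol for labelled images: cells whose
#' observed state is hidden or background become free (their alphabet
#' restricted to the hidden states plus background), every other cell is
#' clamped to its observed state, and clamped Metropolis sampling yields a
#' per-cell probability map for each hidden state.
#'
#' @param grid the observed `state_grid` (hidden cells typically appear as
#'   background).
#' @param params fitted or generating `potts_parameters`.
#' @param hidden integer vector of hidden states.
#' @param truth optional ground-truth `state_grid` (or matrix) to score
#'   against: the summary is the mean predicted probability of the true
#'   hidden state at its true locations, versus the base rate a uniform
#'   guesser over free cells would score.
#' @param restrict_alphabet keep free cells on the hidden+background
#'   alphabet (default, the published protocol); `FALSE` frees the full
#'   alphabet.
#' @param n_samples,burn_in,stride,seed Metropolis settings.
#' @return list with `maps` (named list of rows x cols probability
#'   matrices, one per hidden state), `free` (logical matrix), `score`,
#'   `base_rate` (both `NULL` without truth).
#' @export
infer_missing_states <- function(grid, params, hidden, truth = NULL,
                                 restrict_alphabet = TRUE,
                                 n_samples = 1000L, burn_in = 1000L,
                                 stride = 5L, seed = NULL) {
  stopifnot(inherits(grid, "state_grid"))
  hidden <- sort(unique(as.integer(hidden)))
  if (length(hidden) == 0L) stop("nothing hidden: specify at least one hidden state")
  bg <- grid$colors$background_state
  if (length(setdiff(seq_len(params$n_states) - 1L, c(hidden, bg))) == 0L)
    stop("at least one visible non-background state is required")
  R <- nrow(grid$states); C <- ncol(grid$states)
  obs <- as.integer(t(grid$states))          # row-major flat, matches lattice
  free <- obs %in% c(hidden, bg)
  clamped <- ifelse(free, NA_integer_, obs)
  allowed <- if (restrict_alphabet) sort(unique(c(hidden, bg))) else NULL
  marg <- conditional_marginals(params, grid$topology, clamped,
                                allowed_states = allowed,
                                n_samples = n_samples, burn_in = burn_in,
                                stride = stride, seed = seed)
  maps <- lapply(hidden, function(st)
    matrix(marg[, st + 1L], R, C, byrow = TRUE))
  names(maps) <- paste0("state", hidden)
  free_mat <- matrix(free, R, C, byrow = TRUE)
  score <- base_rate <- NULL
  if (!is.null(truth)) {
    tm <- if (inherits(truth, "state_grid")) truth$states else truth
    hid_mask <- matrix(FALSE, R, C)
    probs <- numeric(0)
    for (st in hidden) {
      at <- which(tm == st & free_mat)
      hid_mask[at] <- TRUE
      probs <- c(probs, maps[[paste0("state", st)]][at])
    }
    score <- mean(probs)
    base_rate <- sum(hid_mask) / sum(free_mat)
  }
  list(maps = maps, free = free_mat, score = score, base_rate = base_rate)
}

#' Human-readable interaction report for fitted parameters
#'
#' Tabulates h and J with class labels, flags the strongest attraction (most
#' negative coupling) and repulsions (positive couplings), and carries the
#' standing warnings: under this sign convention positive J is repulsion,
#' and absolute values are gauge-dependent -- only relative comparisons are
#' meaningful.
#'
#' @param params a `potts_parameters` (spatial block is reported).
#' @param colors a [color_classes()] supplying the labels.
#' @return an object of class `coupling_report` with `fields` (data frame),
#'   `couplings` (data frame of unordered pairs), `strongest_attraction`,
#'   `notes`.
#' @export
coupling_report <- function(params, colors = color_classes()) {
  Q <- params$n_states
  stopifnot(colors$n_states == Q)
  lab <- colors$labels
  J <- params$J[[1L]]
  fields <- data.frame(state = seq_len(Q) - 1L, label = lab, h = params$h)
  pi_ <- integer(0); pj <- integer(0)
  for (i in seq_len(Q)) for (j in i:Q) { pi_ <- c(pi_, i); pj <- c(pj, j) }
  couplings <- data.frame(
    state_i = pi_ - 1L, state_j = pj - 1L,
    label_i = lab[pi_], label_j = lab[pj],
    J = J[cbind(pi_, pj)],
    interaction = ifelse(J[cbind(pi_, pj)] > 0, "repulsion", "attraction"))
  k <- which.min(couplings$J)
  structure(list(
    fields = fields, couplings = couplings,
    strongest_attraction = couplings[k, ],
    notes = c("sign convention: positive J = repulsion, negative J = attraction",
              paste("absolute h and J values are gauge-dependent;",
                    "interpret relative values only"))),
    class = "coupling_report")
}

#' @export
print.coupling_report <- function(x, ...) {
  cat("<coupling_report>\nFields:\n")
  print(x$fields, row.names = FALSE)
  cat("Couplings (unordered pairs):\n")
  print(x$couplings, row.names = FALSE)
  cat(sprintf("Strongest attraction: %s-%s (J = %.4g)\n",
              x$strongest_attraction$label_i, x$strongest_attraction$label_j,
              x$strongest_attraction$J))
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}
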