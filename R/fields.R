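# Velocity-field comparison pipeline: regular-grid vector fields, trilinear
# down-sampling, penalized-least-squares smoothing with GCV (the Garcia
# multidimensional spline smoother), and Bland-Altman / Pearson agreement
# statistics.

#' Regular-grid vector field
#'
#' @param u 4-d array (nx x ny x nz x 3) of velocity components, m/s; for
#'   planar data use nz = 1 and a zero third component
#' @param origin physical coordinates of the first voxel center (length 3)
#' @param spacing voxel spacing (length 3), > 0
#' @param mask logical validity array (nx x ny x nz); NULL = all valid
#' @return a `vector_field` object
#' @export
vector_field <- function(u, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                         mask = NULL) {
  stopifnot(length(dim(u)) == 4, dim(u)[4] == 3, all(spacing > 0))
  dims <- dim(u)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  stopifnot(all(dim(mask) == dims))
  if (any(!is.finite(u[array(mask, dim(u))])))
    stop("non-finite velocity inside the validity mask", call. = FALSE)
  structure(list(u = u, origin = origin, spacing = spacing, mask = mask,
                 dims = dims),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  cat("<vector_field> ", paste(x$dims, collapse = " x "),
      " voxels, ", sum(x$mask), " valid\n", sep = "")
  invisible(x)
}

#' Velocity magnitude of a vector field
#' @param field a [vector_field()]
#' @return 3-d array of |u|, NA outside the mask
#' @export
field_magnitude <- function(field) {
  m <- sqrt(field$u[, , , 1]^2 + field$u[, , , 2]^2 + field$u[, , , 3]^2)
  m <- array(m, field$dims)
  m[!field$mask] <- NA_real_
  m
}

#' Down-sample a vector field by trilinear interpolation
#'
#' Interpolates each velocity component of the fine field at the voxel
#' centers of the coarse grid (the acquisition-resolution grid). A coarse
#' voxel is masked invalid when any of its contributing fine voxels is
#' invalid.
#'
#' @param fine a [vector_field()]
#' @param dims coarse grid size (length 3)
#' @param origin,spacing coarse grid geometry; defaults span the fine grid
#' @return a coarse [vector_field()]
#' @export
downsample_field <- function(fine, dims,
                             spacing = (fine$dims - 1) * fine$spacing / pmax(dims - 1, 1),
                             origin = fine$origin) {
  stopifnot(length(dims) == 3)
  # coarse voxel centers in fine-grid index coordinates (1-based)
  ax <- lapply(1:3, function(d) {
    xc <- origin[d] + (seq_len(dims[d]) - 1) * spacing[d]
    idx <- (xc - fine$origin[d]) / fine$spacing[d] + 1
    if (any(idx < 1 - 1e-9 | idx > fine$dims[d] + 1e-9))
      stop("coarse grid extends outside the fine grid", call. = FALSE)
    pmin(pmax(idx, 1), fine$dims[d])
  })
  gi <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  lo <- pmin(floor(gi), matrix(fine$dims - 1L, nrow(gi), 3, byrow = TRUE))
  fr <- gi - lo
  u <- array(0, c(dims, 3))
  ok <- rep(TRUE, nrow(gi))
  for (corner in 0:7) {
    off <- c(corner %% 2, (corner %/% 2) %% 2, corner %/% 4)
    w <- apply(sapply(1:3, function(d)
      if (off[d] == 1) fr[, d] else 1 - fr[, d]), 1, prod)
    ci <- sapply(1:3, function(d) lo[, d] + off[d])
    lin <- ci[, 1] + (ci[, 2] - 1) * fine$dims[1] +
      (ci[, 3] - 1) * fine$dims[1] * fine$dims[2]
    contrib <- w > 1e-12
    ok <- ok & (!contrib | as.vector(fine$mask)[lin])
    for (comp in 1:3) {
      uc <- as.vector(fine$u[, , , comp])[lin]
      uc[!contrib] <- 0
      u[, , , comp] <- u[, , , comp] + array(w * uc, dims)
    }
  }
  vector_field(u, origin = origin, spacing = spacing,
               mask = array(ok, dims))
}

# --- DCT-based penalized least squares smoothing ---------------------------

# orthonormal DCT-II basis matrices, cached per size
.dct_cache <- new.env(parent = emptyenv())
.dct_basis <- function(n) {
  key <- as.character(n)
  if (!is.null(.dct_cache[[key]])) return(.dct_cache[[key]])
  k <- seq_len(n) - 1
  C <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  C[1, ] <- C[1, ] / sqrt(2)
  .dct_cache[[key]] <- C
  C
}

# orthonormal DCT-II / inverse along the first margin of a matrix (n x m)
.dct_mat <- function(x) if (nrow(x) == 1) x else .dct_basis(nrow(x)) %*% x
.idct_mat <- function(d) if (nrow(d) == 1) d else crossprod(.dct_basis(nrow(d)), d)

# apply fn (matrix operator on first margin) along each margin of array a
.apply_sep <- function(a, fn) {
  dims <- dim(a)
  nd <- length(dims)
  for (d in seq_len(nd)) {
    perm <- c(d, setdiff(seq_len(nd), d))
    ap <- aperm(a, perm)
    m <- fn(matrix(ap, dims[d]))
    a <- aperm(array(m, dims[perm]), order(perm))
  }
  a
}

.dctn <- function(a) .apply_sep(a, .dct_mat)
.idctn <- function(a) .apply_sep(a, .idct_mat)

#' Penalized least-squares smoothing of gridded data (GCV)
#'
#' Multidimensional spline-like smoother: the data are transformed with a
#' discrete cosine transform, attenuated by `1 / (1 + s * Lambda^2)` where
#' `Lambda` is the Laplacian eigenvalue array, and transformed back. The
#' smoothing parameter `s` is chosen automatically by generalized
#' cross-validation. Missing values (NA, or `weights == 0`) are imputed
#' iteratively; the robust option iteratively down-weights outliers with a
#' bisquare function of the studentized residuals.
#'
#' @param y numeric array (any dimensionality) with optional NAs
#' @param robust iterate bisquare re-weighting (3 passes)
#' @param s fixed smoothing parameter; NULL (default) selects by GCV
#' @param max_iter imputation iterations
#' @return list(z = smoothed array, s = smoothing parameter used,
#'   gcv = attained GCV score)
#' @export
smooth_pls <- function(y, robust = FALSE, s = NULL, max_iter = 30) {
  if (is.null(dim(y))) dim(y) <- length(y)
  dims <- dim(y)
  miss <- !is.finite(y)
  if (sum(!miss) < 8) stop("need at least 8 valid values", call. = FALSE)
  W <- array(as.numeric(!miss), dims)
  y0 <- y; y0[miss] <- mean(y[!miss])

  # Laplacian eigenvalues of the DCT basis, summed over dimensions
  lam <- array(0, dims)
  for (d in seq_along(dims)) {
    lam_d <- -2 + 2 * cos(pi * (seq_len(dims[d]) - 1) / dims[d])
    lam <- lam + array(lam_d[slice.index(array(0L, dims), d)], dims)
  }
  lam2 <- lam^2
  gamma_of <- function(sv) 1 / (1 + sv * lam2)
  gcv_score <- function(log10s, zcur, wts) {
    G <- gamma_of(10^log10s)
    zh <- .idctn(G * .dctn(wts * (y0 - zcur) + zcur))
    rss <- sum((wts * (y0 - zh))[!miss]^2)
    rss / sum(wts > 0) / (1 - sum(G) / prod(dims))^2
  }

  wts <- W
  z <- y0
  # continuation: with missing data, start from heavy smoothing and relax,
  # so imputed values are diffused in from the observations before the
  # GCV-selected (possibly very light) smoothing takes over
  if (any(miss)) {
    for (sc in 10^seq(3, -3, by = -1))
      for (it in 1:4)
        z <- .idctn(gamma_of(sc) * .dctn(W * (y0 - z) + z))
  }
  s_use <- s; gcv <- NA_real_
  n_pass <- if (robust) 3L else 1L
  for (pass in seq_len(n_pass)) {
    need_iter <- any(miss) || any(wts < 1)
    for (it in seq_len(if (need_iter) max_iter else 1L)) {
      if (is.null(s)) {
        opt <- stats::optimize(gcv_score, c(-8, 8), zcur = z, wts = wts)
        s_use <- 10^opt$minimum
        gcv <- opt$objective
      }
      z_new <- .idctn(gamma_of(s_use) * .dctn(wts * (y0 - z) + z))
      delta <- sqrt(sum((z_new - z)^2) / max(sum(z_new^2), 1e-300))
      z <- z_new
      if (delta < 1e-5) break
    }
    if (robust && pass < n_pass) {
      r <- y0 - z
      mad <- stats::median(abs(r[!miss] - stats::median(r[!miss]))) * 1.4826
      ustud <- r / pmax(1.5 * mad, 1e-12)
      bis <- (1 - (ustud / 4.685)^2)^2
      bis[abs(ustud) > 4.685] <- 0
      wts <- W * bis
    }
  }
  list(z = z, s = s_use, gcv = gcv)
}

#' Smooth a vector field (component-wise penalized least squares)
#'
#' Applies [smooth_pls()] to each velocity component; voxels outside the
#' validity mask are treated as missing and imputed, and the returned field
#' is valid everywhere (spurious/missing vectors replaced by smoothed ones).
#'
#' @param field a [vector_field()]
#' @param robust use robust (outlier-resistant) weighting
#' @param s fixed smoothing parameter (NULL = GCV per component)
#' @return a smoothed [vector_field()]
#' @export
smooth_field <- function(field, robust = FALSE, s = NULL) {
  if (sum(field$mask) < 8) stop("need at least 8 valid voxels", call. = FALSE)
  u <- field$u
  for (comp in 1:3) {
    y <- array(u[, , , comp], field$dims)
    y[!field$mask] <- NA_real_
    u[, , , comp] <- smooth_pls(y, robust = robust, s = s)$z
  }
  vector_field(u, origin = field$origin, spacing = field$spacing,
               mask = array(TRUE, field$dims))
}

# --- agreement statistics ---------------------------------------------------

.paired_values <- function(a, b, mode) {
  if (!all(a$dims == b$dims) || !isTRUE(all.equal(a$spacing, b$spacing)))
    stop("fields are not on identical grids", call. = FALSE)
  m <- a$mask & b$mask
  if (sum(m) < 2) stop("need more than one valid voxel", call. = FALSE)
  if (mode == "magnitude") {
    va <- field_magnitude(a)[m]
    vb <- field_magnitude(b)[m]
  } else {
    comp <- match(mode, c("x", "y", "z"))
    va <- array(a$u[, , , comp], a$dims)[m]
    vb <- array(b$u[, , , comp], b$dims)[m]
  }
  list(a = va, b = vb, n = sum(m))
}

#' Bland-Altman agreement between two fields
#'
#' Voxel-wise differences (`b - a`) over the common validity mask: bias is
#' the mean difference, the limits of agreement are +/- 1.96 standard
#' deviations around it.
#'
#' @param a,b [vector_field()]s on identical grids
#' @param mode `"magnitude"` (default) or a component `"x"`, `"y"`, `"z"`
#' @return an `agreement_report`: bias, loa_half_width, n_voxels
#' @export
bland_altman <- function(a, b, mode = c("magnitude", "x", "y", "z")) {
  mode <- match.arg(mode)
  p <- .paired_values(a, b, mode)
  d <- p$b - p$a
  structure(list(bias = mean(d), loa_half_width = 1.96 * stats::sd(d),
                 pearson_r = NA_real_, r_squared = NA_real_,
                 n_voxels = p$n, mode = mode),
            class = "agreement_report")
}

#' Pearson correlation between two fields
#'
#' Voxel-wise Pearson product-moment correlation over the common mask;
#' the coefficient of determination is `r^2`.
#'
#' @param a,b [vector_field()]s on identical grids
#' @param mode `"magnitude"` (default) or a component
#' @return an `agreement_report`: pearson_r, r_squared, n_voxels
#' @export
field_correlation <- function(a, b, mode = c("magnitude", "x", "y", "z")) {
  mode <- match.arg(mode)
  p <- .paired_values(a, b, mode)
  if (stats::sd(p$a) == 0 || stats::sd(p$b) == 0)
    stop("zero variance in one of the fields", call. = FALSE)
  r <- stats::cor(p$a, p$b)
  structure(list(bias = NA_real_, loa_half_width = NA_real_,
                 pearson_r = r, r_squared = r^2,
                 n_voxels = p$n, mode = mode),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report> mode:", x$mode, " n =", x$n_voxels, "\n")
  if (is.finite(x$bias))
    cat(sprintf("  bias %.4g, limits of agreement +/- %.4g\n",
                x$bias, x$loa_half_width))
  if (is.finite(x$pearson_r))
    cat(sprintf("  Pearson r %.4f, R^2 %.4f\n", x$pearson_r, x$r_squared))
  invisible(x)
}

# --- I/O --------------------------------------------------------------------

#' Write / read a vector field as legacy ASCII structured-points VTK
#'
#' @param field a [vector_field()]
#' @param path file path
#' @return `write_field_vtk` returns `path` invisibly; `read_field_vtk`
#'   returns a [vector_field()] (mask: finite vectors)
#' @export
write_field_vtk <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "coaflow vector field", "ASCII",
               "DATASET STRUCTURED_POINTS",
               paste("DIMENSIONS", paste(field$dims, collapse = " ")),
               paste("ORIGIN", paste(field$origin, collapse = " ")),
               paste("SPACING", paste(field$spacing, collapse = " ")),
               paste("POINT_DATA", prod(field$dims)),
               "VECTORS velocity double"), con)
  u <- field$u
  u[array(!field$mask, dim(u))] <- NaN
  m <- cbind(as.vector(u[, , , 1]), as.vector(u[, , , 2]), as.vector(u[, , , 3]))
  writeLines(paste(m[, 1], m[, 2], m[, 3]), con)
  invisible(path)
}

#' @rdname write_field_vtk
#' @export
read_field_vtk <- function(path) {
  ln <- readLines(path)
  get3 <- function(key, type = as.numeric) {
    type(strsplit(trimws(sub(key, "", ln[grep(paste0("^", key), ln)[1]])),
                  "\\s+")[[1]])
  }
  dims <- get3("DIMENSIONS", as.integer)
  origin <- get3("ORIGIN")
  spacing <- get3("SPACING")
  iv <- grep("^VECTORS", ln)[1]
  vals <- ln[(iv + 1):(iv + prod(dims))]
  m <- matrix(as.numeric(unlist(strsplit(vals, "\\s+"))), ncol = 3, byrow = TRUE)
  u <- array(0, c(dims, 3))
  for (comp in 1:3) u[, , , comp] <- array(m[, comp], dims)
  mask <- array(rowSums(is.finite(m)) == 3, dims)
  u[is.na(u)] <- 0
  vector_field(u, origin, spacing, mask)
}
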