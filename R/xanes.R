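#' Normalised absorption spectrum
#'
#' Container for a normalised XANES spectrum: a strictly increasing energy
#' grid (eV), dimensionless normalised absorbance, a label, and the edge
#' energy E0 to which fitting windows are referenced.
#'
#' @param energy energy grid (eV), strictly increasing.
#' @param absorbance normalised absorbance, finite, same length.
#' @param label spectrum label.
#' @param e0 edge energy (eV).
#' @return a `spectrum` object.
#' @export
xas_spectrum <- function(energy, absorbance, label = "", e0 = NA_real_) {
  stopifnot(length(energy) == length(absorbance), length(energy) >= 1,
            all(is.finite(energy)), all(is.finite(absorbance)))
  if (any(diff(energy) <= 0)) stop("energy grid must be strictly increasing")
  structure(list(energy = as.numeric(energy),
                 absorbance = as.numeric(absorbance),
                 label = label, e0 = e0), class = "xas_spectrum")
}

#' @export
print.xas_spectrum <- function(x, ...) {
  cat(sprintf("XAS spectrum '%s': %d points, %.5g-%.5g eV (E0 = %s)\n",
              x$label, length(x$energy), min(x$energy), max(x$energy),
              format(x$e0)))
  invisible(x)
}

#' Read a two-column spectrum file
#'
#' Whitespace- or comma-separated text with columns energy (eV) and
#' normalised absorbance; lines starting with `#` are comments.
#'
#' @param path file path.
#' @param label,e0 passed to [xas_spectrum]; label defaults to the file name.
#' @return a `xas_spectrum`.
#' @export
read_spectrum <- function(path, label = NULL, e0 = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  m <- do.call(rbind, lapply(parts, function(p) as.numeric(p[1:2])))
  xas_spectrum(m[, 1], m[, 2],
               label = if (is.null(label)) basename(path) else label, e0 = e0)
}

#' Interpolate a spectrum onto a target energy grid
#'
#' Linear interpolation; requests outside the spectrum's span are an error
#' (no extrapolation).
#'
#' @param spectrum a `xas_spectrum`.
#' @param grid target energies (eV) within the spectrum's span.
#' @return a `xas_spectrum` on `grid`.
#' @export
interpolate_to_grid <- function(spectrum, grid) {
  if (min(grid) < min(spectrum$energy) || max(grid) > max(spectrum$energy))
    stop("target grid outside the span of spectrum '", spectrum$label, "'")
  xas_spectrum(grid, approx(spectrum$energy, spectrum$absorbance,
                            xout = grid)$y,
               label = spectrum$label, e0 = spectrum$e0)
}

# Non-negative least squares with an optional sum-to-one equality constraint,
# solved by an active-set method on the KKT system. Singular working sets are
# handled with an SVD pseudo-inverse and flagged by a conditioning warning.
nnls_sum1 <- function(A, y, sum_to_one = TRUE, tol = 1e-10) {
  p <- ncol(A)
  AtA <- crossprod(A); Aty <- crossprod(A, y)
  warned <- FALSE
  psolve <- function(M, b) {
    s <- svd(M)
    pos <- s$d > max(s$d) * 1e-12
    if (!all(pos) && !warned) {
      warning("ill-conditioned reference set; solution is not unique")
      warned <<- TRUE
    }
    s$v[, pos, drop = FALSE] %*%
      ((crossprod(s$u[, pos, drop = FALSE], b)) / s$d[pos])
  }
  solve_free <- function(free) {
    k <- length(free)
    w <- numeric(p)
    if (sum_to_one) {
      K <- rbind(cbind(2 * AtA[free, free, drop = FALSE], rep(1, k)),
                 c(rep(1, k), 0))
      rhs <- c(2 * Aty[free], 1)
      sol <- psolve(K, rhs)
      w[free] <- sol[seq_len(k)]
      list(w = w, lambda = sol[k + 1])
    } else {
      w[free] <- psolve(2 * AtA[free, free, drop = FALSE], 2 * Aty[free])
      list(w = w, lambda = 0)
    }
  }
  free <- seq_len(p)
  for (it in seq_len(10 * p + 10)) {
    sol <- solve_free(free)
    w <- sol$w
    if (any(w[free] < -tol)) {
      drop_i <- free[which.min(w[free])]
      free <- setdiff(free, drop_i)
      if (length(free) == 0) stop("active-set solver emptied the free set")
      next
    }
    w[w < 0] <- 0
    bound <- setdiff(seq_len(p), free)
    if (length(bound)) {
      mu <- 2 * (AtA %*% w - Aty)[bound] + sol$lambda
      if (any(mu < -tol)) {
        free <- sort(c(free, bound[which.min(mu)]))
        next
      }
    }
    return(w)
  }
  stop("active-set solver failed to converge")
}

#' Linear-combination fit of a spectrum against references
#'
#' Expresses a sample spectrum as a mixture of reference spectra over a
#' fitting window relative to the sample's edge energy (default -20 to
#' +30 eV), minimising the sum of squared residuals subject to non-negative
#' weights and (by default) weights summing to one, as used to quantify
#' mineral fractions from normalised XANES. The quality measure is the
#' R-factor, `sum(resid^2) / sum(sample^2)` over the window.
#'
#' @param sample a `xas_spectrum` with finite `e0`.
#' @param references list of >= 2 `xas_spectrum`s covering the window.
#' @param window fitting window (eV relative to `e0`).
#' @param sum_to_one enforce the weights to sum to 1.
#' @return an `lcf_result`: `weights` (named by reference label),
#'   `r_factor`, `window`, `grid`.
#' @examples
#' grid <- seq(6520, 6600, by = 0.5)
#' refs <- lapply(c(6555, 6559, 6562), function(wl)
#'   synth_reference_spectrum(grid, e0 = 6550, whiteline = wl,
#'                            label = paste0("ref", wl)))
#' mix <- xas_spectrum(grid, 0.3 * refs[[1]]$absorbance +
#'                           0.7 * refs[[3]]$absorbance, e0 = 6550)
#' lcf_fit(mix, refs)$weights
#' @export
lcf_fit <- function(sample, references, window = c(-20, 30),
                    sum_to_one = TRUE) {
  stopifnot(inherits(sample, "xas_spectrum"), length(references) >= 2)
  if (!is.finite(sample$e0)) stop("sample spectrum needs a finite e0")
  lo <- sample$e0 + window[1]; hi <- sample$e0 + window[2]
  grid <- sample$energy[sample$energy >= lo & sample$energy <= hi]
  if (length(grid) < length(references) + 1)
    stop("too few sample points inside the fitting window")
  y <- approx(sample$energy, sample$absorbance, xout = grid)$y
  A <- vapply(references, function(r) interpolate_to_grid(r, grid)$absorbance,
              numeric(length(grid)))
  w <- nnls_sum1(A, y, sum_to_one = sum_to_one)
  resid <- y - A %*% w
  labels <- vapply(references, function(r)
    if (nzchar(r$label)) r$label else "", character(1))
  labels[!nzchar(labels)] <- paste0("ref", which(!nzchar(labels)))
  structure(list(weights = setNames(as.numeric(w), labels),
                 r_factor = sum(resid^2) / sum(y^2),
                 window = window, grid = grid,
                 sum_to_one = sum_to_one), class = "lcf_result")
}

#' @export
print.lcf_result <- function(x, ...) {
  cat("Linear-combination fit\n")
  for (i in seq_along(x$weights))
    cat(sprintf("  %-12s %6.2f %%\n", names(x$weights)[i], 100 * x$weights[i]))
  cat(sprintf("  R-factor: %.3g over [%+g, %+g] eV about E0\n",
              x$r_factor, x$window[1], x$window[2]))
  invisible(x)
}

#' Synthetic reference spectrum for testing the LCF machinery
#'
#' An edge-step (error-function) profile with a Gaussian white-line peak:
#' the discriminating feature real oxidation-state references provide (e.g.
#' white lines near 6555, 6559, 6562 eV for Mn(II), Mn(III), Mn(IV)).
#' Synthetic stand-in; not measured data.
#'
#' @param grid energy grid (eV).
#' @param e0 edge energy (eV).
#' @param whiteline white-line peak position (eV).
#' @param step_width,peak_height,peak_width shape parameters (eV, -, eV).
#' @param label spectrum label.
#' @return a `xas_spectrum`.
#' @export
synth_reference_spectrum <- function(grid, e0, whiteline, step_width = 2,
                                     peak_height = 1.2, peak_width = 3,
                                     label = "") {
  step <- stats::pnorm(grid, mean = e0, sd = step_width)
  peak <- peak_height * exp(-0.5 * ((grid - whiteline) / peak_width)^2)
  xas_spectrum(grid, step + peak, label = label, e0 = e0)
}
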