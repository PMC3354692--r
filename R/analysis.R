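#' Coarsen a stack by a named method
#'
#' Dispatches to the four coarsening schemes: `"H"` builds the basic model
#' and applies cuberrille majority coarsening with side `d`; `"FL"`, `"FS"`
#' and `"FT"` are the slice-pairing schemes with voxel length `d`.
#'
#' @param stack An [image_stack()].
#' @param method One of `"H"`, `"FL"`, `"FS"`, `"FT"`.
#' @param d Cuberrille side / voxel length in micrometres.
#' @param enforce_range Enforce the conventional parameter ranges.
#' @return A [voxel_model()].
#' @export
coarsen_stack <- function(stack, method, d, enforce_range = TRUE) {
  method <- match.arg(method, c("H", "FL", "FS", "FT"))
  switch(method,
         H = coarsen_h(build_basic_model(stack), d,
                       enforce_range = enforce_range),
         FL = coarsen_fl(stack, d, enforce_range = enforce_range),
         FS = coarsen_fs(stack, d, enforce_range = enforce_range),
         FT = coarsen_ft(stack, d, enforce_range = enforce_range))
}

#' Relative modulus versus voxel length
#'
#' Computes the apparent modulus of the basic (full-resolution) model and of
#' each coarsened model, and expresses the latter relative to the former:
#' RE(d) = E_app(method, d) / E_app(basic). The basic model itself is the
#' curve's first point — RE = 1 at the native voxel length, definitionally —
#' and RE decays as the voxel length grows.
#'
#' @param stack An [image_stack()].
#' @param method One of `"H"`, `"FL"`, `"FS"`, `"FT"`.
#' @param d_values Voxel lengths (um), each valid for the method.
#' @param mat A [material_props()].
#' @param load A [load_case()].
#' @param basic_e_app Optional precomputed basic-model apparent modulus
#'   (GPa), to avoid re-solving when looping over methods.
#' @param ... Passed to [assemble_and_solve()].
#' @return A tibble of class `re_curve` with columns `method`, `d_um`,
#'   `e_app_gpa`, `re`, ordered by `d_um`; the basic modulus is attached as
#'   attribute `basic_e_app_gpa`.
#' @export
relative_modulus_curve <- function(stack, method, d_values,
                                   mat = material_props(),
                                   load = load_case(),
                                   basic_e_app = NULL, ...) {
  method <- match.arg(method, c("H", "FL", "FS", "FT"))
  if (is.null(basic_e_app)) {
    basic <- solve_model(build_basic_model(stack), mat, load, ...)
    basic_e_app <- basic$e_app_gpa
  }
  if (!is.numeric(basic_e_app) || basic_e_app <= 0)
    stop("basic model has zero apparent modulus; relative curve undefined",
         call. = FALSE)
  d_values <- sort(d_values)
  e_app <- purrr::map_dbl(d_values, function(d) {
    model <- coarsen_stack(stack, method, d)
    # a model whose load-bearing structure collapses at this resolution
    # (no bone left, or no component spanning the platens) has zero
    # apparent modulus rather than being an analysis failure
    tryCatch(
      solve_model(model, mat, load, ...)$e_app_gpa,
      error = function(e) {
        if (grepl("no bone voxels|loading face", conditionMessage(e))) 0
        else stop(e)
      })
  })
  out <- tibble::tibble(method = method,
                        d_um = c(stack$pixel_size, d_values),
                        e_app_gpa = c(basic_e_app, e_app),
                        re = c(1, e_app / basic_e_app))
  attr(out, "basic_e_app_gpa") <- basic_e_app
  class(out) <- c("re_curve", class(out))
  out
}

#' Ordinary least-squares line fit
#'
#' Fits `y = a * x + b` and reports the slope, intercept and coefficient of
#' determination. A response with zero variance yields `a = 0` and, by
#' convention, `r2 = 0`.
#'
#' @param x,y Numeric vectors of equal length, at least 3 points; `x` must
#'   not be constant.
#' @return An object of class `bone_fit`: list with `a`, `b`, `r2`, `form`
#'   (`"linear"`), `n`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("`x` is constant; slope undefined",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  a <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  new_bone_fit(a, b, r2, "linear", length(x))
}

#' Logarithmic fit of the relative-modulus curve
#'
#' Fits `RE = a * ln(d) + b` by least squares over the points with voxel
#' length at most `d_max` (300 um by default, the range over which the
#' logarithmic description of the decay holds).
#'
#' @param d_values Voxel lengths in micrometres.
#' @param re_values Relative moduli at those lengths.
#' @param d_max Upper voxel length for inclusion in the fit (um).
#' @return A `bone_fit` with `form = "log"`.
#' @export
log_fit <- function(d_values, re_values, d_max = 300) {
  stopifnot(length(d_values) == length(re_values))
  keep <- d_values <= d_max
  if (sum(keep) < 3L)
    stop("fewer than 3 points at or below d_max; cannot fit", call. = FALSE)
  lf <- linear_fit(log(d_values[keep]), re_values[keep])
  new_bone_fit(lf$a, lf$b, lf$r2, "log", lf$n)
}

new_bone_fit <- function(a, b, r2, form, n) {
  structure(list(a = a, b = b, r2 = r2, form = form, n = n),
            class = "bone_fit")
}

#' @export
print.bone_fit <- function(x, ...) {
  rhs <- if (x$form == "log") "ln(x)" else "x"
  cat(sprintf("<bone_fit> y = %.6g * %s + %.6g   (R^2 = %.4f, n = %d)\n",
              x$a, rhs, x$b, x$r2, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.bone_fit <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept"), estimate = c(x$a, x$b))
}

#' @export
glance.bone_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, n = x$n, form = x$form)
}

#' Regression of modulus-decay slopes on structural indices
#'
#' For each coarsening method, regresses the per-sample absolute value of
#' the logarithmic decay slope |a| (from [log_fit()] of the RE curve) on
#' each structural index. Porous, thin-strutted specimens lose stiffness
#' faster under coarsening, so |a| typically falls with increasing BV/TV,
#' Tb.Th or Vm and the reported regression slopes come out negative.
#'
#' @param samples A data frame with one row per (sample, method): columns
#'   `sample_id`, `method`, `a` (the log-fit slope) and one numeric column
#'   per structural index (e.g. `bv_tv`, `tb_th_mm`, `tb_n_per_mm`,
#'   `vm_mm3`).
#' @param indices Names of the index columns to regress on; defaults to all
#'   numeric columns other than `a`.
#' @return A tibble with one row per (method, index): `method`, `index`,
#'   `a` (regression slope), `b` (intercept), `r2`, and `a_abs = |a|`.
#' @export
slope_index_table <- function(samples, indices = NULL) {
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("method", "a") %in% names(samples)))
  if (is.null(indices)) {
    num <- names(samples)[vapply(samples, is.numeric, logical(1))]
    indices <- setdiff(num, c("a", "d_um"))
  }
  if (length(indices) == 0L) stop("no index columns found", call. = FALSE)
  methods <- unique(samples$method)
  grid <- tidyr::expand_grid(method = methods, index = indices)
  purrr::pmap_dfr(grid, function(method, index) {
    sub <- samples[samples$method == method, , drop = FALSE]
    if (nrow(sub) < 3L)
      stop("need at least 3 samples per method", call. = FALSE)
    fit <- linear_fit(sub[[index]], abs(sub$a))
    tibble::tibble(method = method, index = index, a = fit$a, b = fit$b,
                   r2 = fit$r2, a_abs = abs(fit$a))
  })
}

#' Plot relative-modulus curves
#'
#' @param object An `re_curve` tibble (or several row-bound together, with a
#'   `method` and optionally a `sample_id` column).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.re_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$d_um, y = .data$re,
                                        colour = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "voxel length d (µm)", y = "relative modulus RE",
                  colour = "method") +
    ggplot2::theme_minimal()
  if ("sample_id" %in% names(df))
    p <- p + ggplot2::facet_wrap(~sample_id)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot slope-versus-index relationships
#'
#' Scatter of per-sample absolute decay slopes |a| against a structural
#' index, one panel per coarsening method, with the least-squares line.
#'
#' @param samples The per-(sample, method) table accepted by
#'   [slope_index_table()].
#' @param index Name of the index column to plot against.
#' @return A ggplot.
#' @export
plot_slope_index <- function(samples, index = "bv_tv") {
  df <- tibble::as_tibble(samples)
  stopifnot(index %in% names(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[index]], y = abs(.data$a))) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::facet_wrap(~method, scales = "free_y") +
    ggplot2::labs(x = index, y = "|a| (log-fit decay slope)") +
    ggplot2::theme_minimal()
}
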