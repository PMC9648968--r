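#' Equidistant parameter grid under the effective-rate constraint
#'
#' Cartesian product of equidistant points per parameter (convention:
#' `range * j / m` for `j = 1..m`, zero excluded, upper endpoint included),
#' filtered by the effective transcription rate constraint
#' `rho * sigma_on / (sigma_on + sigma_off) < threshold`.
#'
#' @param n_points Points per dimension (>= 2).
#' @param max_sigma_off,max_sigma_on,max_rho Upper range per parameter
#'   (1/min); defaults 150, 150, 250.
#' @param threshold Effective-rate constraint (1/min), default 100; strict
#'   inequality. Use `Inf` to disable.
#' @return A data.frame with columns `sigma_off`, `sigma_on`, `rho`,
#'   `f_on`, `effective_rate`, in deterministic row order.
#' @examples
#' nrow(generate_parameter_grid(2, threshold = 100))  # 5 of the 8 survive
#' @export
generate_parameter_grid <- function(n_points = 10L, max_sigma_off = 150,
                                    max_sigma_on = 150, max_rho = 250,
                                    threshold = 100) {
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  pts <- function(mx) mx * seq_len(n_points) / n_points
  g <- expand.grid(sigma_off = pts(max_sigma_off), sigma_on = pts(max_sigma_on),
                   rho = pts(max_rho), KEEP.OUT.ATTRS = FALSE)
  g$f_on <- g$sigma_on / (g$sigma_on + g$sigma_off)
  g$effective_rate <- g$rho * g$f_on
  g <- g[g$effective_rate < threshold, , drop = FALSE]
  if (nrow(g) == 0) stop("no parameter sets survive the constraint", call. = FALSE)
  rownames(g) <- NULL
  g
}

#' Per-parameter relative errors and their mean
#'
#' `|theta* - theta| / |theta|` per parameter, and the mean relative error
#' (MRE) over the estimated parameters -- the benchmark's accuracy metric.
#'
#' @param theta_star Estimated [rate_params].
#' @param theta_true True [rate_params]; all entries must be nonzero.
#' @return A list with `errors` (named vector over sigma_on, sigma_off, rho)
#'   and `mre`.
#' @examples
#' relative_errors(rate_params(1.1, 0.9, 1), rate_params(1, 1, 1))$mre
#' @export
relative_errors <- function(theta_star, theta_true) {
  stopifnot(inherits(theta_star, "rate_params"), inherits(theta_true, "rate_params"))
  nm <- c("sigma_on", "sigma_off", "rho")
  est <- unlist(theta_star[nm])
  tru <- unlist(theta_true[nm])
  if (any(tru == 0)) stop("true parameters must be nonzero", call. = FALSE)
  err <- abs(est - tru) / abs(tru)
  list(errors = err, mre = mean(err))
}

#' Paired mature/nascent parameter-recovery benchmark
#'
#' For each grid point: simulate mature counts (optionally with per-cell
#' log-normal perturbation of the initiation rate at coefficient of
#' variation `noise_cv`) and nascent signal bins (noise-free), fit both with
#' [fit_kinetics()], and record per-parameter relative errors and the mean
#' relative error (MRE) of each fit. Individual fit failures are recorded,
#' not fatal. Fully reproducible from `(grid, n_cells, seed_base)`.
#'
#' @param grid A data.frame from [generate_parameter_grid()] (or any frame
#'   with `sigma_off`, `sigma_on`, `rho`).
#' @param n_cells Cells simulated per dataset (default 1e4).
#' @param noise_cv External noise on the mature initiation rate: 0, 0.05 or
#'   0.10 in the study conditions (any non-negative value accepted).
#' @param seed_base Base seed; point i uses seeds derived from
#'   `seed_base + i`.
#' @param scale A [scale_cfg] fixing d, tau and the geometry.
#' @param control A [fit_control]; benchmark runs usually reduce the budget.
#' @param checkpoint Optional CSV path; completed rows are appended and
#'   re-used on a rerun (resumable).
#' @return A data.frame with the true parameters, fitted parameters, per-
#'   parameter relative errors, `mre_mature`, `mre_nascent`, `f_on_true` and
#'   a `nascent_better` flag.
#' @export
run_benchmark <- function(grid, n_cells = 1e4, noise_cv = 0, seed_base = 1L,
                          scale = scale_cfg(),
                          control = fit_control(pop = 25, max_gen = 80,
                                                patience = 25, restarts = 1),
                          checkpoint = NULL) {
  stopifnot(all(c("sigma_off", "sigma_on", "rho") %in% names(grid)))
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.csv(checkpoint)
  }
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (!is.null(done) && i %in% done$point) {
      rows[[i]] <- done[done$point == i, , drop = FALSE]
      next
    }
    rows[[i]] <- .benchmark_point(i, grid[i, ], n_cells, noise_cv,
                                  seed_base, scale, control)
    if (!is.null(checkpoint)) {
      utils::write.csv(do.call(rbind, rows[seq_len(i)]), checkpoint,
                       row.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.benchmark_point <- function(i, row, n_cells, noise_cv, seed_base, scale, control) {
  truth <- rate_params(row$sigma_on, row$sigma_off, row$rho)
  seed_i <- seed_base + 7919L * i

  rho_cells <- if (noise_cv > 0) {
    perturb_initiation_rates(truth$rho, noise_cv, n_cells, seed = seed_i + 1L)
  } else NULL
  mat <- simulate_mature_cells(mature_model(truth, d = scale$d),
                               sim_config(n_cells, seed_i + 2L),
                               rho_per_cell = rho_cells)
  nas <- simulate_nascent_cells(nascent_model(truth, tau = scale$tau,
                                              geometry = scale$geometry),
                                sim_config(n_cells, seed_i + 3L))

  ctl <- control
  ctl$seed <- seed_i + 4L
  fit_m <- tryCatch(
    fit_kinetics(observed_dataset(mat, "mature-counts"), scale, control = ctl),
    error = function(e) NULL)
  ctl$seed <- seed_i + 5L
  fit_n <- tryCatch(
    fit_kinetics(observed_dataset(nas$bin, "nascent-bins"), scale, control = ctl),
    error = function(e) NULL)

  err <- function(fit) {
    if (is.null(fit)) return(list(errors = c(sigma_on = NA_real_,
                                             sigma_off = NA_real_,
                                             rho = NA_real_), mre = NA_real_))
    relative_errors(fit$theta_star, truth)
  }
  em <- err(fit_m); en <- err(fit_n)
  fd <- derived_quantities(truth)
  data.frame(
    point = i,
    sigma_on_true = truth$sigma_on, sigma_off_true = truth$sigma_off,
    rho_true = truth$rho, f_on_true = fd$fraction_on,
    burst_true = fd$burst_size,
    sigma_on_mature = if (is.null(fit_m)) NA else fit_m$theta_star$sigma_on,
    sigma_off_mature = if (is.null(fit_m)) NA else fit_m$theta_star$sigma_off,
    rho_mature = if (is.null(fit_m)) NA else fit_m$theta_star$rho,
    sigma_on_nascent = if (is.null(fit_n)) NA else fit_n$theta_star$sigma_on,
    sigma_off_nascent = if (is.null(fit_n)) NA else fit_n$theta_star$sigma_off,
    rho_nascent = if (is.null(fit_n)) NA else fit_n$theta_star$rho,
    err_sigma_on_mature = em$errors[["sigma_on"]],
    err_sigma_off_mature = em$errors[["sigma_off"]],
    err_rho_mature = em$errors[["rho"]],
    err_sigma_on_nascent = en$errors[["sigma_on"]],
    err_sigma_off_nascent = en$errors[["sigma_off"]],
    err_rho_nascent = en$errors[["rho"]],
    mre_mature = em$mre, mre_nascent = en$mre,
    nascent_better = !is.na(en$mre) && !is.na(em$mre) && en$mre < em$mre
  )
}

#' Median relative errors binned by the true fraction of ON time
#'
#' Groups benchmark records into windows `[x - 0.05, x + 0.05]` around the
#' requested centers of the true fraction of ON time and reports the median
#' relative error per parameter (including the burst size and the inferred
#' fON as derived parameters) for the mature and nascent fits.
#'
#' @param records Output of [run_benchmark()].
#' @param bin_centers Window centers, default `seq(0.1, 0.9, by = 0.1)`.
#' @return A data.frame: one row per (center, data kind), medians per
#'   parameter; empty bins give `NA` rather than an error.
#' @export
binned_median_relative_error <- function(records,
                                         bin_centers = seq(0.1, 0.9, by = 0.1)) {
  if (nrow(records) == 0) stop("records are empty", call. = FALSE)
  derived_err <- function(est_on, est_off, est_rho, true_on, true_off, true_rho) {
    b_est <- est_rho / est_off
    b_true <- true_rho / true_off
    f_est <- est_on / (est_on + est_off)
    f_true <- true_on / (true_on + true_off)
    list(burst = abs(b_est - b_true) / abs(b_true),
         f_on = abs(f_est - f_true) / abs(f_true))
  }
  out <- list()
  for (x in bin_centers) {
    sel <- records[abs(records$f_on_true - x) <= 0.05 + 1e-12, , drop = FALSE]
    for (kindt in c("mature", "nascent")) {
      if (nrow(sel) == 0) {
        med <- rep(NA_real_, 5)
      } else {
        de <- derived_err(sel[[paste0("sigma_on_", kindt)]],
                          sel[[paste0("sigma_off_", kindt)]],
                          sel[[paste0("rho_", kindt)]],
                          sel$sigma_on_true, sel$sigma_off_true, sel$rho_true)
        med <- c(stats::median(sel[[paste0("err_sigma_on_", kindt)]], na.rm = TRUE),
                 stats::median(sel[[paste0("err_sigma_off_", kindt)]], na.rm = TRUE),
                 stats::median(sel[[paste0("err_rho_", kindt)]], na.rm = TRUE),
                 stats::median(de$burst, na.rm = TRUE),
                 stats::median(de$f_on, na.rm = TRUE))
      }
      out[[length(out) + 1L]] <- data.frame(
        f_on_center = x, kind = kindt, n = nrow(sel),
        med_err_sigma_on = med[1], med_err_sigma_off = med[2],
        med_err_rho = med[3], med_err_burst_size = med[4],
        med_err_f_on = med[5])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
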