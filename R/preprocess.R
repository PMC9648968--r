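#' Classify cells into G1/G2 from integrated DNA-stain intensity
#'
#' Fits a two-component Gaussian mixture (unequal variances, EM via mclust)
#' to the integrated nuclear DNA-stain intensities of a cell population.
#' Cells within one standard deviation of the lower-mean component are
#' labeled G1, within one standard deviation of the higher-mean component
#' G2, and everything else (including cells falling in both windows)
#' undetermined.
#'
#' @param intensities Numeric vector of integrated DNA-stain intensities.
#' @param min_cells Minimum population size for a stable fit (default 50).
#' @param window_sd Half-width of the classification window in component
#'   standard deviations (default 1).
#' @return A list with `labels` (factor with levels G1, G2, undetermined)
#'   and `fit`, a `cell_cycle_fit` holding per-component `mean`, `sd`,
#'   `weight`.
#' @examples
#' dna <- simulate_dna_content(500, 400, seed = 3)
#' cc <- classify_cell_cycle(dna$intensity)
#' table(cc$labels)
#' @export
classify_cell_cycle <- function(intensities, min_cells = 50L, window_sd = 1) {
  if (length(intensities) < min_cells) {
    stop("need at least ", min_cells, " cells for the mixture fit", call. = FALSE)
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  mc <- tryCatch(
    mclust::Mclust(intensities, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(mc)) {
    stop("Gaussian mixture EM did not converge on these intensities", call. = FALSE)
  }
  mu <- mc$parameters$mean
  sd_ <- sqrt(mc$parameters$variance$sigmasq)
  if (length(sd_) == 1L) sd_ <- rep(sd_, 2)  # guard: equal-variance degenerate
  w <- mc$parameters$pro
  ord <- order(mu)
  mu <- mu[ord]; sd_ <- sd_[ord]; w <- w[ord]

  fit <- structure(list(mean = mu, sd = sd_, weight = w,
                        window_sd = window_sd), class = "cell_cycle_fit")

  if (abs(mu[2] - mu[1]) < 1e-8 * max(mu)) {
    warning("mixture fit is degenerate (equal means); all cells undetermined",
            call. = FALSE)
    labels <- factor(rep("undetermined", length(intensities)),
                     levels = c("G1", "G2", "undetermined"))
    return(list(labels = labels, fit = fit))
  }

  in_g1 <- abs(intensities - mu[1]) <= window_sd * sd_[1]
  in_g2 <- abs(intensities - mu[2]) <= window_sd * sd_[2]
  labels <- rep("undetermined", length(intensities))
  labels[in_g1 & !in_g2] <- "G1"
  labels[in_g2 & !in_g1] <- "G2"   # both windows -> undetermined (tie rule)
  list(labels = factor(labels, levels = c("G1", "G2", "undetermined")),
       fit = fit)
}

#' @export
print.cell_cycle_fit <- function(x, ...) {
  cat(sprintf("<cell_cycle_fit> G1: N(%.3g, %.3g) w=%.2f | G2: N(%.3g, %.3g) w=%.2f\n",
              x$mean[1], x$sd[1], x$weight[1], x$mean[2], x$sd[2], x$weight[2]))
  invisible(x)
}

#' Normalize transcription-site intensities to single-mRNA units
#'
#' Divides each cell's brightest-nuclear-spot intensity by the dataset-wide
#' median cytoplasmic spot intensity (the intensity of one mature mRNA), and
#' assigns the integer signal bin by ceiling: normalized signal in (i-1, i]
#' maps to bin i, zero to bin 0 -- the convention of [signal_bin_pmf()].
#'
#' @param records A data.frame with columns `brightest_nuclear_intensity` and
#'   `median_cytoplasmic_intensity`.
#' @return The input with added columns `normalized_intensity` and `bin`.
#' @export
normalize_transcription_site <- function(records) {
  need <- c("brightest_nuclear_intensity", "median_cytoplasmic_intensity")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  med <- stats::median(records$median_cytoplasmic_intensity, na.rm = TRUE)
  if (!is.finite(med) || med <= 0) {
    stop("dataset-wide cytoplasmic median must be positive", call. = FALSE)
  }
  records$normalized_intensity <- records$brightest_nuclear_intensity / med
  records$bin <- ceiling_bin(records$normalized_intensity)
  records
}

#' Assemble mature mRNA counts from spot-count records
#'
#' Cells with zero detected spots are excluded (they reflect segmentation or
#' permeabilization failures rather than silent cells). With
#' `include_ts = FALSE` one spot per cell -- the transcription site, counted
#' as one mRNA regardless of intensity -- is removed (floored at zero).
#'
#' @param records A data.frame with a `spot_count` column.
#' @param include_ts Keep the transcription site in the count (default TRUE).
#' @return Integer vector of per-cell mature counts.
#' @examples
#' assemble_mature_counts(data.frame(spot_count = c(0, 3, 5)))  # 3 5
#' @export
assemble_mature_counts <- function(records, include_ts = TRUE) {
  if (!"spot_count" %in% names(records)) {
    stop("records must have a spot_count column", call. = FALSE)
  }
  if (nrow(records) == 0) stop("records are empty", call. = FALSE)
  counts <- records$spot_count[records$spot_count > 0]
  counts <- as.integer(counts)
  if (include_ts) counts else pmax(counts - 1L, 0L)
}

.cell_table_columns <- c("cell_id", "spot_count", "brightest_nuclear_intensity",
                         "median_cytoplasmic_intensity",
                         "integrated_dna_intensity", "phase")

#' Read / write per-cell tables
#'
#' CSV schema: `cell_id`, `spot_count` (non-negative integer),
#' `brightest_nuclear_intensity`, `median_cytoplasmic_intensity`,
#' `integrated_dna_intensity` (non-negative), `phase` (G1, G2, undetermined
#' or unassigned). `write_cell_table` followed by `load_cell_table` is the
#' identity.
#'
#' @param path CSV file path.
#' @param records A data.frame following the schema.
#' @return `load_cell_table` returns the validated data.frame;
#'   `write_cell_table` returns `path` invisibly.
#' @export
load_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.cell_table_columns, names(df))
  if (length(miss)) {
    stop("cell table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), .cell_table_columns)
  if (length(extra)) {
    stop("cell table has unexpected column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("spot_count", "brightest_nuclear_intensity",
                "median_cytoplasmic_intensity", "integrated_dna_intensity")) {
    if (!is.numeric(df[[col]])) {
      stop("column ", col, " must be numeric", call. = FALSE)
    }
    if (any(!is.finite(df[[col]])) || any(df[[col]] < 0)) {
      stop("column ", col, " must be finite and non-negative", call. = FALSE)
    }
  }
  if (any(df$spot_count != round(df$spot_count))) {
    stop("column spot_count must be integer-valued", call. = FALSE)
  }
  bad <- !df$phase %in% c("G1", "G2", "undetermined", "unassigned")
  if (any(bad)) {
    stop("column phase has invalid value(s): ",
         paste(unique(df$phase[bad]), collapse = ", "), call. = FALSE)
  }
  df$spot_count <- as.integer(df$spot_count)
  df[.cell_table_columns]
}

#' @rdname load_cell_table
#' @export
write_cell_table <- function(records, path) {
  miss <- setdiff(.cell_table_columns, names(records))
  if (length(miss)) {
    stop("records are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(records[.cell_table_columns], path, row.names = FALSE)
  invisible(path)
}

#' Build a synthetic per-cell table from the simulators
#'
#' Convenience glue for tests and the command-line interface: simulates
#' mature counts, nascent signal and DNA content for a mixed G1/G2-like
#' population and emits a schema-conforming cell table.
#'
#' @param spec_mature A [mature_model].
#' @param spec_nascent A [nascent_model].
#' @param n_cells Number of cells.
#' @param seed Integer seed.
#' @param dna_means,dna_sds Gaussian mixture settings for the DNA stain.
#' @return A data.frame following the [load_cell_table()] schema.
#' @export
synthesize_cell_table <- function(spec_mature, spec_nascent, n_cells,
                                  seed = 1L, dna_means = c(100, 200),
                                  dna_sds = c(10, 20)) {
  cfg <- sim_config(n_cells, seed)
  counts <- simulate_mature_cells(spec_mature, cfg)
  nas <- simulate_nascent_cells(spec_nascent, sim_config(n_cells, seed + 1L))
  n_g1 <- ceiling(n_cells / 2)
  dna <- simulate_dna_content(n_g1, n_cells - n_g1, dna_means, dna_sds,
                              seed = seed + 2L)
  med_cyto <- 150  # arbitrary fluorescence units per single mRNA
  data.frame(
    cell_id = seq_len(n_cells),
    spot_count = as.integer(counts),
    brightest_nuclear_intensity = nas$signal * med_cyto,
    median_cytoplasmic_intensity = rep(med_cyto, n_cells),
    integrated_dna_intensity = pmax(dna$intensity[sample.int(n_cells)], 0),
    phase = "unassigned"
  )
}
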