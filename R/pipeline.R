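#' Pipeline configuration
#'
#' Validated bundle of every tunable the end-to-end runner uses. All
#' defaults follow the package's canonical analysis: four bands, six window
#' lengths at 20% overlap, 1 s edge trim, 4th-order zero-phase Butterworth,
#' anatomical left/right partition, clipped high-order weights, pooled
#' t-tests with BH FDR at q* = 0.05.
#'
#' @param bands Named list of [band_spec()]s.
#' @param schemes Named list of [window_scheme()]s.
#' @param trim_s Edge trim in seconds.
#' @param filter_order Butterworth order.
#' @param partition Named channel -> module map.
#' @param weight_mode `"clip"` or `"absolute"` (high-order weights).
#' @param length_map `"inverse"` or `"neglog"` (weight -> length).
#' @param crossband_mode `"one_to_one"` or `"nm"`.
#' @param state_features `"vector"` (per-node PCs) or `"mean"` (scalar).
#' @param dynamics_orders Orders fed to the state pipeline (`"low"`,
#'   `"high"` or both).
#' @param kmeans_replicates K-means restarts.
#' @param q_star FDR level.
#' @param variant t-test variant.
#' @param seed Base seed for the stochastic stages (state clustering).
#' @param run_dynamics,run_crossband Stage switches.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(bands = default_bands(),
                            schemes = default_window_schemes(),
                            trim_s = 1,
                            filter_order = 4L,
                            partition = default_partition(),
                            weight_mode = c("clip", "absolute"),
                            length_map = c("inverse", "neglog"),
                            crossband_mode = c("one_to_one", "nm"),
                            state_features = c("vector", "mean"),
                            dynamics_orders = c("low", "high"),
                            kmeans_replicates = 50L,
                            q_star = 0.05,
                            variant = c("pooled", "welch"),
                            seed = 1L,
                            run_dynamics = TRUE,
                            run_crossband = TRUE) {
  weight_mode <- match.arg(weight_mode)
  length_map <- match.arg(length_map)
  crossband_mode <- match.arg(crossband_mode)
  state_features <- match.arg(state_features)
  variant <- match.arg(variant)
  stopifnot(all(dynamics_orders %in% c("low", "high")),
            trim_s >= 0, q_star > 0, q_star < 1, kmeans_replicates >= 1)
  for (b in bands) stopifnot(inherits(b, "band_spec"))
  for (s in schemes) stopifnot(inherits(s, "window_scheme"))
  structure(
    list(bands = bands, schemes = schemes, trim_s = trim_s,
         filter_order = as.integer(filter_order), partition = partition,
         weight_mode = weight_mode, length_map = length_map,
         crossband_mode = crossband_mode, state_features = state_features,
         dynamics_orders = dynamics_orders,
         kmeans_replicates = as.integer(kmeans_replicates),
         q_star = q_star, variant = variant, seed = as.integer(seed),
         run_dynamics = isTRUE(run_dynamics),
         run_crossband = isTRUE(run_crossband)),
    class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "<pipeline_config: %d bands, %d schemes, trim %g s, %s weights, q* = %g, seed %d>\n",
    length(x$bands), length(x$schemes), x$trim_s, x$weight_mode, x$q_star,
    x$seed))
  invisible(x)
}

# static + dynamic + cross-band analysis of one subject
process_subject <- function(rec, config, subject_seed) {
  tensors <- band_phases(rec, config$bands, trim_s = config$trim_s,
                         order = config$filter_order)
  sid <- rec$subject_id
  # static within-band low- and high-order networks
  lows <- lapply(tensors, lofc)
  highs <- lapply(lows, function(l) suppressWarnings(hofc(l)))
  edges <- dplyr::bind_rows(
    lapply(c(lows, highs), function(m) {
      dplyr::mutate(as_tibble(m), scope = "within", subject_id = sid)
    }))
  metrics <- dplyr::bind_rows(lapply(c(lows, highs), function(m) {
    dplyr::mutate(metric_set(m, mode = config$weight_mode,
                             length_map = config$length_map),
                  subject_id = sid)
  }))
  out <- list(edges = edges, metrics = metrics)
  # dynamics: state entropy per scheme x band x order
  if (config$run_dynamics) {
    ent <- list()
    k <- 0L
    for (ord in config$dynamics_orders) {
      for (b in names(tensors)) {
        for (sn in names(config$schemes)) {
          k <- k + 1L
          series <- dynamic_networks(tensors[[b]], config$schemes[[sn]],
                                     order = ord)
          feats <- participation_series(series, config$partition,
                                        mode = config$weight_mode)
          if (config$state_features == "mean") {
            feats <- rowMeans(feats)
          }
          states <- classify_states(feats,
                                    replicates = config$kmeans_replicates,
                                    seed = derive_seed(subject_seed, 7L, k))
          ent[[k]] <- tibble::tibble(
            subject_id = sid, band = b, order = ord, scheme = sn,
            n_windows = length(states), se = state_entropy(states))
        }
      }
    }
    out$entropy <- dplyr::bind_rows(ent)
  }
  # between-frequency networks, supra-adjacency and global metrics
  if (config$run_crossband) {
    pr <- band_pairs(config$bands)
    btw_low <- list()
    btw_high <- list()
    xedges <- list()
    for (r in seq_len(nrow(pr))) {
      key <- paste(pr$band_a[r], pr$band_b[r], sep = "|")
      bl <- cross_band_lofc(tensors[[pr$band_a[r]]], tensors[[pr$band_b[r]]],
                            mode = config$crossband_mode)
      btw_low[[key]] <- bl
      btw_high[[key]] <- suppressWarnings(hofc_asymmetric(bl))
      xedges[[key]] <- dplyr::bind_rows(
        dplyr::mutate(as_tibble(bl), scope = "between", subject_id = sid),
        dplyr::mutate(as_tibble(btw_high[[key]]), scope = "between",
                      subject_id = sid))
    }
    out$edges <- dplyr::bind_rows(out$edges, dplyr::bind_rows(xedges))
    supra_low <- assemble_supra(lows, btw_low)
    gl <- dplyr::mutate(cross_band_global(supra_low), order = "low",
                        subject_id = sid)
    supra_high <- assemble_supra(highs, lapply(btw_high, symmetrize_cm))
    gh <- dplyr::mutate(cross_band_global(supra_high), order = "high",
                        subject_id = sid)
    out$crossband_global <- dplyr::bind_rows(gl, gh)
    out$supra <- list(low = supra_low, high = supra_high)
  }
  out
}

# high-order network of a (possibly asymmetric) band-pair matrix: columns
# of the matrix as given are correlated (documented convention)
hofc_asymmetric <- function(lofc_in) {
  W <- lofc_in$W
  n <- nrow(W)
  if (n < 4L) stop("hofc needs n >= 4 nodes", call. = FALSE)
  eps <- 1e-12
  H <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      keep <- setdiff(seq_len(n), c(i, j))
      zi <- atanh(pmin(pmax(W[keep, i], -(1 - eps)), 1 - eps))
      zj <- atanh(pmin(pmax(W[keep, j], -(1 - eps)), 1 - eps))
      H[i, j] <- H[j, i] <-
        if (stats::sd(zi) == 0 || stats::sd(zj) == 0) 0 else
          stats::cor(zi, zj)
    }
  }
  connectivity_matrix(H, "high", "between", lofc_in$band, lofc_in$band_b,
                      node_labels = lofc_in$node_labels)
}

# already-symmetric high-order band-pair blocks pass through unchanged
symmetrize_cm <- function(m) {
  m$W <- (m$W + t(m$W)) / 2
  m
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes, per subject: band decomposition -> static low/high-order
#' networks and graph metrics -> sliding-window dynamics with
#' participation-coefficient state classification and state entropy ->
#' between-frequency networks, supra-adjacency and cross-band global
#' metrics; then, when the cohort has exactly two groups, the full set of
#' FDR-corrected between-group comparisons. Deterministic for a fixed
#' config and cohort.
#'
#' @param cohort An `eeg_cohort` from [simulate_cohort()], or a plain list
#'   of [eeg_recording()]s.
#' @param config A [pipeline_config()].
#' @param keep_supra Keep each subject's supra-adjacency matrices in the
#'   bundle (memory-heavy; default `FALSE`).
#' @return A `results_bundle`: list of tibbles `edges`, `metrics`,
#'   `entropy`, `crossband_global`, the `manifest`, `comparisons` (when two
#'   groups) and the `config` snapshot.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         keep_supra = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(cohort, "eeg_cohort")) {
    recs <- cohort$recordings
    manifest <- cohort$manifest
  } else {
    recs <- cohort
    manifest <- tibble::tibble(
      subject_id = vapply(recs, function(r) r$subject_id, character(1)),
      group = vapply(recs, function(r) r$group, character(1)),
      seed = NA_integer_)
  }
  per <- vector("list", length(recs))
  for (s in seq_along(recs)) {
    res <- tryCatch(
      process_subject(recs[[s]], config,
                      subject_seed = derive_seed(config$seed, 1L, s)),
      error = function(e) {
        stop(sprintf("pipeline failed for subject '%s': %s",
                     recs[[s]]$subject_id, conditionMessage(e)),
             call. = FALSE)
      })
    if (!keep_supra) res$supra <- NULL
    per[[s]] <- res
  }
  bundle <- structure(list(
    edges = dplyr::bind_rows(lapply(per, `[[`, "edges")),
    metrics = dplyr::bind_rows(lapply(per, `[[`, "metrics")),
    entropy = if (config$run_dynamics)
      dplyr::bind_rows(lapply(per, `[[`, "entropy")) else NULL,
    crossband_global = if (config$run_crossband)
      dplyr::bind_rows(lapply(per, `[[`, "crossband_global")) else NULL,
    supra = if (keep_supra) lapply(per, `[[`, "supra") else NULL,
    manifest = manifest,
    config = config), class = "results_bundle")
  if (length(unique(manifest$group)) == 2L) {
    bundle$comparisons <- compare_cohorts(bundle, q_star = config$q_star,
                                          variant = config$variant)
  }
  bundle
}

#' @export
print.results_bundle <- function(x, ...) {
  cat(sprintf("<results_bundle: %d subjects, %d edge rows, %d metric rows%s>\n",
              nrow(x$manifest), nrow(x$edges), nrow(x$metrics),
              if (!is.null(x$comparisons))
                sprintf(", %d comparison families",
                        length(x$comparisons) - 1L) else ""))
  invisible(x)
}

#' Write a results bundle to labeled CSV files
#'
#' @param bundle A `results_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in c("edges", "metrics", "entropy", "crossband_global",
               "manifest")) {
    if (is.null(bundle[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(bundle[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(bundle$comparisons)) {
    p <- file.path(dir, "comparisons.csv")
    utils::write.csv(bundle$comparisons$summary, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
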