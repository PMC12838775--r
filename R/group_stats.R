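#' Two-sample t-test (pooled or Welch)
#'
#' Closed-form independent-sample t statistic with explicit zero-variance
#' policy: if both groups are constant with equal means, `t = 0, p = 1`; if
#' constant with unequal means, `t = +/-Inf, p = 0` (flagged via the `df`
#' being returned as `NA`-free but degenerate handling documented).
#'
#' @param a,b Numeric vectors, each with >= 2 finite values.
#' @param variant `"pooled"` (Student, default) or `"welch"`.
#' @return List with `t`, `p` (two-sided), `df`.
#' @examples
#' two_sample_t(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6)) # t = -3.674, df = 4
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L || !all(is.finite(c(a, b)))) {
    stop("each group needs >= 2 finite values", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  diff <- mean(a) - mean(b)
  if (variant == "pooled") {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- if (se > 0) {
      (va / na + vb / nb)^2 /
        ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    } else na + nb - 2
  }
  if (se == 0) {
    if (diff == 0) return(list(t = 0, p = 1, df = df))
    return(list(t = sign(diff) * Inf, p = 0, df = df))
  }
  t <- diff / se
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted values (`min` over ranks `j >= rank` of `m p_(j) / j`,
#' capped at 1) and the significance mask at level `q_star`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q_star FDR level (default 0.05).
#' @return List with `q` (adjusted values, input order) and `mask` (logical).
#' @export
fdr_bh <- function(p, q_star = 0.05) {
  if (length(p) == 0L) return(list(q = numeric(0), mask = logical(0)))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, mask = q <= q_star)
}

#' Compare two groups item-by-item within a family
#'
#' Tidy engine behind every between-group analysis in the package: takes a
#' long table of per-subject values (one row per subject x item), runs an
#' independent two-sample t-test per item, applies Benjamini-Hochberg FDR
#' within the family, and records the direction of the group difference
#' (sign of `mean(group_a) - mean(group_b)`).
#'
#' @param data Data frame with (at least) the columns named by `item`,
#'   `value` and `group`.
#' @param item,value,group Column names (strings).
#' @param group_a,group_b The two group labels to compare; default the first
#'   two levels encountered (in order of appearance).
#' @param family_id Label for this comparison family.
#' @param q_star FDR level.
#' @param variant t-test variant (see [two_sample_t()]).
#' @return A `group_comparison`: tibble with one row per item (`item`, `n_a`,
#'   `n_b`, `mean_a`, `mean_b`, `t`, `df`, `p`, `q`, `significant`,
#'   `direction`), with attributes `family_id`, `q_star`, `variant`,
#'   `group_a`, `group_b`.
#' @export
compare_groups <- function(data, item = "item", value = "value",
                           group = "group", group_a = NULL, group_b = NULL,
                           family_id = "family", q_star = 0.05,
                           variant = "pooled") {
  stopifnot(is.data.frame(data),
            all(c(item, value, group) %in% names(data)))
  gl <- unique(as.character(data[[group]]))
  if (is.null(group_a)) group_a <- gl[1]
  if (is.null(group_b)) group_b <- gl[2]
  if (is.na(group_a) || is.na(group_b) || group_a == group_b) {
    stop("need two distinct group labels", call. = FALSE)
  }
  items <- unique(data[[item]])
  rows <- lapply(items, function(it) {
    sel <- data[[item]] == it
    va <- data[[value]][sel & data[[group]] == group_a]
    vb <- data[[value]][sel & data[[group]] == group_b]
    tt <- two_sample_t(va, vb, variant)
    tibble::tibble(item = it, n_a = length(va), n_b = length(vb),
                   mean_a = mean(va), mean_b = mean(vb),
                   t = tt$t, df = tt$df, p = tt$p)
  })
  out <- dplyr::bind_rows(rows)
  adj <- fdr_bh(out$p, q_star)
  out$q <- adj$q
  out$significant <- adj$mask
  out$direction <- dplyr::case_when(
    out$mean_a > out$mean_b ~ paste(group_a, ">", group_b),
    out$mean_a < out$mean_b ~ paste(group_a, "<", group_b),
    TRUE ~ "equal"
  )
  structure(out, family_id = family_id, q_star = q_star, variant = variant,
            group_a = group_a, group_b = group_b,
            class = c("group_comparison", class(out)))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison '%s': %s vs %s, %d items, %d significant (q* = %g)>\n",
              attr(x, "family_id"), attr(x, "group_a"), attr(x, "group_b"),
              nrow(x), sum(x$significant), attr(x, "q_star")))
  NextMethod()
}

#' @describeIn compare_groups Tidy per-item results (plain tibble with a
#'   `family` column and significance stars: * for 0.01 < p < 0.05, ** for
#'   0.001 < p < 0.01, *** below).
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x))
  out$family <- attr(x, "family_id")
  out$stars <- dplyr::case_when(
    out$p < 0.001 ~ "***",
    out$p < 0.01 ~ "**",
    out$p < 0.05 ~ "*",
    TRUE ~ ""
  )
  dplyr::relocate(out, "family")
}

#' @describeIn compare_groups One-row summary of the family.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    family = attr(x, "family_id"),
    group_a = attr(x, "group_a"),
    group_b = attr(x, "group_b"),
    n_items = nrow(x),
    n_significant = sum(x$significant),
    min_q = if (nrow(x)) min(x$q) else NA_real_,
    q_star = attr(x, "q_star"),
    variant = attr(x, "variant")
  )
}

#' Between-group comparison of a full results bundle
#'
#' Runs [compare_groups()] over every analysis family of a
#' [run_pipeline()] bundle: within-band edges (28 unique edges per band x
#' order), graph metric sets (4 metrics per band x order), state entropy
#' (one value per window scheme, family per band x order), band-pair edges
#' and cross-band global metrics (6 pairs per order). FDR is applied within
#' each family; raw and adjusted p-values are both reported so alternative
#' correction scopes can be audited.
#'
#' @param bundle A `results_bundle` from [run_pipeline()] whose manifest has
#'   exactly two groups.
#' @param q_star FDR level.
#' @param variant t-test variant.
#' @return Named list of `group_comparison` objects (one per family), with
#'   a combined tidy tibble in `$summary`.
#' @export
compare_cohorts <- function(bundle, q_star = 0.05, variant = "pooled") {
  stopifnot(inherits(bundle, "results_bundle"))
  groups <- unique(bundle$manifest$group)
  if (length(groups) != 2L) {
    stop("compare_cohorts needs exactly two groups", call. = FALSE)
  }
  fams <- list()
  add_families <- function(df, split_cols, item_col, label) {
    if (is.null(df) || nrow(df) == 0) return(invisible(NULL))
    df <- dplyr::left_join(df, bundle$manifest[, c("subject_id", "group")],
                           by = "subject_id")
    keys <- dplyr::distinct(df[, split_cols, drop = FALSE])
    for (r in seq_len(nrow(keys))) {
      sel <- rep(TRUE, nrow(df))
      for (cn in split_cols) sel <- sel & df[[cn]] == keys[[cn]][r]
      fid <- paste(c(label, unlist(keys[r, ])), collapse = ":")
      fams[[fid]] <<- compare_groups(df[sel, ], item = item_col,
                                     value = "value", group = "group",
                                     group_a = groups[1], group_b = groups[2],
                                     family_id = fid, q_star = q_star,
                                     variant = variant)
    }
  }
  edges <- bundle$edges
  if (!is.null(edges)) {
    w <- dplyr::rename(dplyr::filter(edges, .data$scope == "within"),
                       value = "weight")
    add_families(w, c("band", "order"), "edge", "edges")
    b <- dplyr::rename(dplyr::filter(edges, .data$scope == "between"),
                       value = "weight")
    if (nrow(b)) {
      b$pair <- paste(b$band, b$band_b, sep = "-")
      add_families(b, c("pair", "order"), "edge", "xedges")
    }
  }
  if (!is.null(bundle$metrics)) {
    # disconnected networks have CPL = Inf; compare the finite-subnetwork
    # mean instead (identical to CPL whenever the network is connected)
    m0 <- bundle$metrics
    m0$cpl <- m0$cpl_finite
    m <- tidyr::pivot_longer(m0, cols = c("cc", "cpl", "ge", "le"),
                             names_to = "metric", values_to = "value")
    m <- dplyr::filter(m, is.finite(.data$value))
    add_families(m, c("band", "order"), "metric", "metrics")
  }
  if (!is.null(bundle$entropy)) {
    e <- dplyr::rename(bundle$entropy, value = "se")
    add_families(e, c("band", "order"), "scheme", "entropy")
  }
  if (!is.null(bundle$crossband_global)) {
    g <- dplyr::rename(
      dplyr::filter(bundle$crossband_global, .data$pair != "overall"),
      value = "global_metric")
    add_families(g, "order", "pair", "global")
  }
  fams$summary <- dplyr::bind_rows(lapply(
    fams[setdiff(names(fams), "summary")], tidy))
  fams
}
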