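# Noise-resilience benchmark: replace a growing fraction of a protein
# family with random proteins drawn from a disjoint pool, recompute every
# configured coherence metric, and summarize similarity as a function of
# the replacement level. The range (max - min) of the per-level means is
# the metric's empirical resolution.

#' Replace a fraction of a family with random pool proteins
#'
#' Keeps `N - k` members sampled without replacement from the family and
#' adds `k` proteins sampled without replacement from the pool, where
#' `k = round(fraction * N)` with ties rounded half up. Uses the current
#' RNG state; seed beforehand (or via [run_assay()]) for reproducibility.
#'
#' @param family A `protein_set`.
#' @param pool A `protein_set` disjoint from `family` supplying the
#'   replacement proteins.
#' @param fraction Replacement fraction in `[0, 1]`; 0 returns the family
#'   unchanged.
#' @return A `protein_set` with exactly `length(family$members)` members
#'   and no duplicates.
#' @export
degenerate <- function(family, pool, fraction) {
  family <- as_protein_set(family)
  pool <- as_protein_set(pool)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1) {
    stop("fraction must be a single number in [0, 1]")
  }
  overlap <- intersect(family$members, pool$members)
  if (length(overlap)) {
    stop("pool must be disjoint from the family; shared protein(s): ",
         paste(utils::head(overlap, 5), collapse = ", "))
  }
  n <- length(family$members)
  k <- as.integer(floor(fraction * n + 0.5 + 1e-9))  # round half up
  if (k == 0L) return(family)
  if (length(pool$members) < k) {
    stop("pool too small: need ", k, " replacement proteins, have ",
         length(pool$members))
  }
  keep <- family$members[sample.int(n, n - k)]
  repl <- pool$members[sample.int(length(pool$members), k)]
  protein_set(c(keep, repl), label = family$label)
}

#' Configuration for a degeneration assay
#'
#' @param levels Replacement fractions, ascending within `[0, 1]`.
#' @param iterations Random replacement draws per level.
#' @param seed Base seed; iteration `i` at the `l`-th level runs under
#'   seed `seed + 100003 * l + i`, one independent substream each.
#' @param min_family_size Families smaller than this are skipped (with a
#'   message) rather than assayed.
#' @param metrics Metric names among `"agreement"`, `"ui"`, `"gic"`,
#'   `"mui"`, `"mgic"`, and/or a named list of functions
#'   `function(set, corpus, ontology, ic, alpha)` returning a scalar in
#'   `[0, 1]` (the plug-in hook for external metrics).
#' @param alpha Significance level passed to the hybrid metrics.
#' @return Object of class `assay_config`.
#' @export
assay_config <- function(levels = seq(0, 1, by = 0.1), iterations = 100L,
                         seed = 1L, min_family_size = 20L,
                         metrics = c("agreement", "ui", "gic", "mui", "mgic"),
                         alpha = 0.05) {
  if (any(levels < 0 | levels > 1) || is.unsorted(levels)) {
    stop("levels must be ascending fractions within [0, 1]")
  }
  if (iterations < 1L) stop("iterations must be >= 1")
  structure(
    list(levels = levels, iterations = as.integer(iterations),
         seed = as.integer(seed), min_family_size = as.integer(min_family_size),
         metrics = metrics, alpha = alpha),
    class = "assay_config"
  )
}

# Resolve configured metrics into a named list of
# function(set, corpus, ontology, ic, alpha) -> scalar.
metric_registry <- function(metrics) {
  builtin <- list(
    agreement = function(set, corpus, ontology, ic, alpha) {
      agreement(set, corpus)
    },
    ui = function(set, corpus, ontology, ic, alpha) {
      set_similarity(set, corpus, "ui")$value
    },
    gic = function(set, corpus, ontology, ic, alpha) {
      set_similarity(set, corpus, "gic", ic = ic)$value
    },
    mui = function(set, corpus, ontology, ic, alpha) {
      m_ui(set, corpus, ontology, alpha = alpha)$value
    },
    mgic = function(set, corpus, ontology, ic, alpha) {
      m_gic(set, corpus, ontology, ic = ic, alpha = alpha)$value
    }
  )
  out <- list()
  if (is.character(metrics)) {
    unknown <- setdiff(metrics, names(builtin))
    if (length(unknown)) {
      stop("unknown metric(s): ", paste(unknown, collapse = ", "))
    }
    out <- builtin[metrics]
  } else if (is.list(metrics)) {
    for (nm in names(metrics)) {
      m <- metrics[[nm]]
      out[[nm]] <- if (is.function(m)) m else builtin[[m]]
    }
  } else {
    stop("metrics must be a character vector or a named list")
  }
  out
}

#' Run a degeneration assay on one family
#'
#' For every replacement level and iteration, degenerates the family with
#' [degenerate()] under an iteration-indexed seed substream, scores every
#' configured metric on the degenerated set, and reports the per-level
#' mean and standard deviation. Fully reproducible from `config$seed`.
#'
#' @param family A `protein_set` (at least `config$min_family_size`
#'   members, otherwise skipped with a message and `NULL` returned).
#' @param pool A `protein_set` disjoint from `family`.
#' @param corpus An `annotation_corpus` covering family and pool.
#' @param ontology The `go_ontology`.
#' @param ic Information-content table; computed from `corpus` when `NULL`
#'   and a metric needs it.
#' @param config An [assay_config()].
#' @return A data frame of class `degeneration_profile` with columns
#'   `family`, `metric`, `level`, `mean`, `sd`, `n`.
#' @export
run_assay <- function(family, pool, corpus, ontology, ic = NULL,
                      config = assay_config()) {
  family <- as_protein_set(family)
  pool <- as_protein_set(pool)
  stopifnot(inherits(config, "assay_config"))
  if (length(family$members) < config$min_family_size) {
    message("family '", family$label, "' skipped: size ",
            length(family$members), " below the minimum of ",
            config$min_family_size)
    return(NULL)
  }
  funs <- metric_registry(config$metrics)
  if (is.null(ic) && any(names(funs) %in% c("gic", "mgic"))) {
    ic <- ic_table(corpus)
  }

  rows <- list()
  for (li in seq_along(config$levels)) {
    level <- config$levels[[li]]
    scores <- matrix(NA_real_, nrow = config$iterations, ncol = length(funs),
                     dimnames = list(NULL, names(funs)))
    for (it in seq_len(config$iterations)) {
      sub_seed <- config$seed + 100003L * li + it
      degenerated <- withr::with_seed(sub_seed, degenerate(family, pool, level))
      for (nm in names(funs)) {
        scores[it, nm] <- funs[[nm]](degenerated, corpus, ontology, ic,
                                     config$alpha)
      }
    }
    for (nm in names(funs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        family = family$label, metric = nm, level = level,
        mean = mean(scores[, nm]),
        sd = stats::sd(scores[, nm]),
        n = config$iterations,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$sd[is.na(out$sd)] <- 0  # single iteration
  class(out) <- c("degeneration_profile", "data.frame")
  out
}

#' Empirical resolution of metrics from degeneration profiles
#'
#' For each family and metric, takes the range (maximum minus minimum) of
#' the mean similarity across replacement levels, then averages the ranges
#' across families.
#'
#' @param profile A `degeneration_profile`-shaped data frame with columns
#'   `family`, `metric`, `level`, `mean` (profiles from several families
#'   may be row-bound together).
#' @param metric Optional metric name(s) to restrict to.
#' @return Named numeric vector of across-family mean ranges, one entry
#'   per metric (a bare scalar when a single metric is requested).
#' @export
resolution <- function(profile, metric = NULL) {
  if (!is.data.frame(profile) ||
      !all(c("family", "metric", "level", "mean") %in% names(profile))) {
    stop("profile must be a data frame with columns family, metric, ",
         "level, mean")
  }
  if (!nrow(profile)) stop("empty profile")
  if (!is.null(metric)) {
    profile <- profile[profile$metric %in% metric, , drop = FALSE]
    if (!nrow(profile)) stop("no rows for metric(s): ",
                             paste(metric, collapse = ", "))
  }
  groups <- split(profile, list(profile$metric, profile$family), drop = TRUE)
  if (any(vapply(groups, function(d) length(unique(d$level)), integer(1)) <
          2L)) {
    stop("each family needs means at >= 2 levels to define a range")
  }
  ranges <- vapply(groups, function(d) max(d$mean) - min(d$mean), numeric(1))
  mets <- vapply(groups, function(d) d$metric[[1]], character(1))
  agg <- tapply(ranges, mets, mean)
  out <- stats::setNames(as.numeric(agg), names(agg))
  if (length(out) == 1L) unname(out) else out
}

#' Plot degeneration profiles
#'
#' Similarity as a function of the replacement fraction, one line per
#' metric, faceted by family. Requires ggplot2.
#'
#' @param profile A `degeneration_profile`.
#' @return A ggplot object.
#' @export
plot_degeneration <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_degeneration requires the ggplot2 package")
  }
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$level, y = .data$mean,
                               colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(x = "fraction of proteins replaced",
                  y = "mean similarity", colour = "metric") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
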