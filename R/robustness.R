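#' Lin's concordance correlation coefficient
#'
#' Agreement between two measurements of the same quantity:
#' `CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with
#' population (1/n) moments. Unlike Pearson's r, the CCC penalises
#' location and scale shifts, so `ccc(x, y) <= |cor(x, y)|` always.
#'
#' @param x,y numeric vectors of equal length (at least 3), not both
#'   constant.
#' @return The CCC, a number in `[-1, 1]`.
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("Need at least 3 paired observations.")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("Inputs must be finite.")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  if (vx == 0 && vy == 0) abort("Both inputs are constant; CCC undefined.")
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (vx + vy + (mx - my)^2)
}

#' Feature robustness across pre-processing sets
#'
#' For every feature and every non-reference parameter set, computes the
#' CCC between the feature measured under that set and under the reference
#' set, across the shared subjects. Features whose CCC drops below 0.9 for
#' any comparison are flagged as poorly robust (the conventional cut-off
#' below which agreement is considered poor).
#'
#' @param tables named list of feature tibbles (same subjects, same
#'   features), e.g. from [extract_all_sets()].
#' @param reference name of the reference set; defaults to `"64-5-111"`
#'   when present, otherwise the first table.
#' @return A `ccc_report`: tibble with columns `feature`, `set`, `ccc`,
#'   plus attributes `reference` and a per-feature summary (`mean_ccc`,
#'   `min_ccc`, `poor`) available via [tidy()].
#' @export
ccc_report <- function(tables, reference = NULL) {
  if (is.null(names(tables)) || any(names(tables) == "")) {
    abort("`tables` must be a named list of feature tables.")
  }
  if (is.null(reference)) {
    reference <- if ("64-5-111" %in% names(tables)) "64-5-111" else names(tables)[1]
  }
  if (!reference %in% names(tables)) {
    abort(sprintf("Reference set '%s' not found.", reference))
  }
  feats <- setdiff(names(tables[[reference]]), c("subject_id", "label"))
  ref_ids <- tables[[reference]]$subject_id
  for (nm in names(tables)) {
    if (!identical(tables[[nm]]$subject_id, ref_ids)) {
      abort(sprintf("Subjects of set '%s' do not match the reference.", nm))
    }
    if (!all(feats %in% names(tables[[nm]]))) {
      abort(sprintf("Set '%s' is missing features.", nm))
    }
  }
  others <- setdiff(names(tables), reference)
  rows <- purrr::map_dfr(others, function(nm) {
    tibble(
      feature = feats,
      set = nm,
      ccc = vapply(feats, function(f) {
        ccc(tables[[reference]][[f]], tables[[nm]][[f]])
      }, numeric(1))
    )
  })
  structure(rows, class = c("ccc_report", class(rows)), reference = reference)
}

#' @export
tidy.ccc_report <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(x), .data$feature),
    mean_ccc = mean(.data$ccc),
    min_ccc = min(.data$ccc),
    poor = any(.data$ccc < 0.9),
    .groups = "drop"
  )
}

#' @export
glance.ccc_report <- function(x, ...) {
  s <- tidy(x)
  tibble(
    reference = attr(x, "reference"),
    n_sets = length(unique(x$set)) + 1L,
    n_features = nrow(s),
    n_poor = sum(s$poor)
  )
}

#' @export
autoplot.ccc_report <- function(object, ...) {
  df <- as_tibble(object)
  df$feature <- factor(df$feature, levels = rev(unique(df$feature)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ccc, y = .data$feature)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0.9, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("CCC vs reference set %s", attr(object, "reference")),
      y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Pearson correlation matrix averaged over parameter sets
#'
#' Computes the feature-by-feature Pearson correlation matrix within each
#' parameter set and averages entrywise across sets. A feature that is
#' constant within a set contributes 0 to the affected entries for that
#' set (with a warning). A display ordering from average-linkage (UPGMA)
#' hierarchical clustering on `1 - r` is attached.
#'
#' @param tables named list of feature tibbles.
#' @return An `avg_cor_matrix`: the averaged matrix with attributes
#'   `order` (UPGMA leaf order) and `n_sets`.
#' @export
averaged_correlation_matrix <- function(tables) {
  if (length(tables) < 1L) abort("Need at least one table.")
  feats <- setdiff(names(tables[[1]]), c("subject_id", "label"))
  acc <- matrix(0, length(feats), length(feats),
                dimnames = list(feats, feats))
  for (nm in seq_along(tables)) {
    X <- as.matrix(tables[[nm]][, feats])
    sds <- apply(X, 2, sd)
    if (any(sds == 0)) {
      warn(sprintf(
        "Constant feature(s) in set %s: %s; their correlations set to 0.",
        names(tables)[nm] %||% nm,
        paste(feats[sds == 0], collapse = ", ")
      ))
    }
    r <- suppressWarnings(cor(X))
    r[!is.finite(r)] <- 0
    diag(r) <- 1
    acc <- acc + r
  }
  m <- acc / length(tables)
  hc <- stats::hclust(stats::as.dist(1 - m), method = "average")
  structure(m, class = c("avg_cor_matrix", "matrix"),
            order = feats[hc$order], n_sets = length(tables))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
tidy.avg_cor_matrix <- function(x, ...) {
  m <- unclass(x)
  attr(m, "order") <- NULL; attr(m, "n_sets") <- NULL
  out <- as_tibble(as.data.frame(as.table(m)), .name_repair = "minimal")
  names(out) <- c("feature_a", "feature_b", "correlation")
  as_tibble(out)
}

#' @export
autoplot.avg_cor_matrix <- function(object, ...) {
  ord <- attr(object, "order")
  df <- tidy(object)
  df$feature_a <- factor(df$feature_a, levels = ord)
  df$feature_b <- factor(df$feature_b, levels = rev(ord))
  ggplot2::ggplot(df, ggplot2::aes(.data$feature_a, .data$feature_b,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#b2182b",
                                  mid = "white", high = "#2166ac") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean r")
}
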