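#' Noise-replacement permutation importance
#'
#' For each feature the model uses, replaces its test-set column with
#' seeded Gaussian noise matched to the column's mean and standard deviation
#' (`noise = "shuffle"` permutes the column within itself instead),
#' re-scores accuracy, and reports importance = baseline accuracy minus the
#' mean replaced accuracy over `R` repeats. A feature the model ignores
#' scores near zero.
#'
#' @param model A `nirs_model`.
#' @param test Test `feature_table` rows.
#' @param R Number of noise replacements per feature (>= 1).
#' @param seed Integer seed; same seed, identical importances.
#' @param noise `"gaussian"` (marginal-matched noise, the default reading of
#'   replacement by "noise signals") or `"shuffle"` (within-column
#'   permutation).
#' @return A `feature_importance` object: named importance vector, baseline
#'   accuracy, `R`.
#' @export
permutation_importance_noise <- function(model, test, R = 10L, seed = 1L,
                                         noise = c("gaussian", "shuffle")) {
  noise <- match.arg(noise)
  if (R < 1L) stop_invalid("importance", "R must be at least 1")
  baseline <- evaluate_model(model, test)$accuracy
  X <- as.data.frame(test)
  n <- nrow(X)
  imp <- with_seed(seed, {
    vapply(model$features, function(feat) {
      col <- X[[feat]]
      acc <- vapply(seq_len(R), function(r) {
        Xr <- X
        Xr[[feat]] <- if (noise == "gaussian") {
          stats::rnorm(n, mean = mean(col), sd = stats::sd(col))
        } else {
          sample(col)
        }
        mean(predict(model, Xr) == factor(test$label, levels = model$levels))
      }, 0)
      baseline - mean(acc)
    }, 0)
  })
  structure(list(importance = imp, baseline = baseline, R = R, seed = seed),
            class = "feature_importance")
}

#' Aggregate feature importance onto brain regions
#'
#' Negative importances are floored at zero, then each temporal feature's
#' importance is added to its channel's ROI and each connectivity feature's
#' importance is split between its two channels' ROIs according to
#' `connectivity_split` (a same-ROI pair contributes fully to that ROI).
#' The resulting per-ROI scores are normalized to sum to 1 whenever any
#' importance is positive.
#'
#' @param imp A `feature_importance`.
#' @param layout A `probe_layout`.
#' @param connectivity_split Fraction of a connectivity feature's importance
#'   credited to the first channel's ROI (default 0.5, an even split).
#' @return A `roi_importance_map`: normalized score per ROI plus the
#'   normalization constant (the floored importance total).
#' @export
aggregate_roi <- function(imp, layout = default_layout(),
                          connectivity_split = 0.5) {
  md <- feature_metadata(layout)
  rownames(md) <- md$name
  unknown <- setdiff(names(imp$importance), md$name)
  if (length(unknown)) {
    stop_invalid("importance", paste("feature not in layout metadata:",
                                     unknown[1L]))
  }
  scores <- stats::setNames(numeric(6L), roi_labels())
  vals <- pmax(imp$importance, 0)
  for (feat in names(vals)) {
    v <- vals[[feat]]
    info <- md[feat, ]
    if (info$kind == "temporal") {
      scores[info$roi_a] <- scores[info$roi_a] + v
    } else {
      scores[info$roi_a] <- scores[info$roi_a] + connectivity_split * v
      scores[info$roi_b] <- scores[info$roi_b] + (1 - connectivity_split) * v
    }
  }
  total <- sum(scores)
  structure(list(scores = if (total > 0) scores / total else scores,
                 normalization = total),
            class = "roi_importance_map")
}

#' @export
print.roi_importance_map <- function(x, ...) {
  cat("<roi_importance_map>\n")
  for (r in names(x$scores)) cat(sprintf("  %-7s %.3f\n", r, x$scores[r]))
  invisible(x)
}

#' ROI importance for every transfer cell
#'
#' Computes a normalized ROI importance map for each (training group,
#' testing group) combination of a fitted [transfer_matrix()]: the training
#' group's model is probed with noise-replacement importance on the testing
#' group's rows and the result aggregated onto ROIs.
#'
#' @param tm A `transfer_matrix`.
#' @param test Test `feature_table` rows.
#' @param layout A `probe_layout`.
#' @param R Noise replacements per feature.
#' @param seed Integer seed.
#' @return A 3 x 3 nested list of `roi_importance_map`s
#'   (`[[train_group]][[test_group]]`), class `roi_importance_grid`.
#' @export
importance_grid <- function(tm, test, layout = default_layout(),
                            R = 10L, seed = 1L) {
  groups <- tm$groups
  seeds <- derive_seeds(seed, length(groups)^2)
  grid <- list()
  i <- 0L
  for (g in groups) {
    grid[[g]] <- list()
    for (h in groups) {
      i <- i + 1L
      te <- filter_group(test, h)
      fi <- permutation_importance_noise(tm$models[[g]], te, R = R,
                                         seed = seeds[i])
      grid[[g]][[h]] <- aggregate_roi(fi, layout)
    }
  }
  structure(grid, class = "roi_importance_grid")
}

#' Flatten an importance grid to long-format rows
#'
#' @param x A `roi_importance_grid`.
#' @param ... Unused.
#' @return Data frame with columns `train_group`, `test_group`, `roi`,
#'   `normalized_score`.
#' @export
as.data.frame.roi_importance_grid <- function(x, ...) {
  rows <- list()
  for (g in names(x)) {
    for (h in names(x[[g]])) {
      s <- x[[g]][[h]]$scores
      rows[[length(rows) + 1L]] <- data.frame(
        train_group = g, test_group = h, roi = names(s),
        normalized_score = unname(s))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
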