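#' Matching dissimilarity between two category patterns
#'
#' The k-modes distance: the number of attribute positions at which two
#' categorical vectors differ. Code 0 ("none") is an ordinary category here,
#' so a drug present in one pattern and absent in the other counts as one
#' mismatch.
#'
#' @param a,b Equal-length integer vectors of category codes.
#' @return Integer count of mismatching positions.
#' @export
#' @examples
#' matching_distance(c(1, 2, 3, 0), c(1, 5, 3, 0))
matching_distance <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  sum(a != b)
}

# Pattern input -> integer matrix of codes
as_pattern_matrix <- function(x) {
  if (inherits(x, "unique_patterns")) {
    cols <- attr(x, "pattern_cols")
    x <- x$patterns[cols]
  }
  if (is.data.frame(x)) {
    keys <- intersect(c("patient_id", "date", "hour", "pattern_id", "multiplicity"),
      names(x)
    )
    cols <- attr(x, "pattern_cols") %||% setdiff(names(x), keys)
    x <- x[cols]
    x <- as.matrix(x)
  }
  storage.mode(x) <- "integer"
  x
}

# n x k matrix of matching distances from each row of x to each mode
mode_distances <- function(x, modes) {
  n <- nrow(x)
  k <- nrow(modes)
  d <- matrix(0L, n, k)
  for (j in seq_len(k)) {
    d[, j] <- rowSums(x != matrix(modes[j, ], n, ncol(x), byrow = TRUE))
  }
  d
}

# attribute-wise most frequent code, ties -> lowest code
column_modes <- function(x, ncat) {
  apply(x, 2, function(col) which.max(tabulate(col + 1L, nbins = ncat)) - 1L)
}

# Cao (2009) density-based initialization: density from attribute
# frequencies, then greedily maximize density * min-distance to chosen modes.
cao_init <- function(x, k) {
  n <- nrow(x)
  p <- ncol(x)
  dens <- rep(0, n)
  for (a in seq_len(p)) {
    counts <- table(x[, a])
    dens <- dens + as.numeric(counts[as.character(x[, a])])
  }
  dens <- dens / (n * p)
  centers <- integer(k)
  centers[1] <- which.max(dens)
  if (k > 1) {
    for (j in 2:k) {
      dmin <- apply(mode_distances(x, x[centers[seq_len(j - 1)], , drop = FALSE]),
        1, min
      )
      score <- dens * dmin
      score[centers[seq_len(j - 1)]] <- -Inf
      centers[j] <- which.max(score)
    }
  }
  x[centers, , drop = FALSE]
}

kmodes_single <- function(x, modes, max_iter, ncat) {
  n <- nrow(x)
  labels <- integer(n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d <- mode_distances(x, modes)
    new_labels <- max.col(-d, ties.method = "first")
    # re-seed any emptied cluster with the point farthest from its mode
    for (j in which(tabulate(new_labels, nbins = nrow(modes)) == 0)) {
      far <- which.max(d[cbind(seq_len(n), new_labels)])
      new_labels[far] <- j
    }
    if (identical(new_labels, labels) || iter > max_iter) {
      labels <- new_labels
      break
    }
    labels <- new_labels
    for (j in seq_len(nrow(modes))) {
      members <- x[labels == j, , drop = FALSE]
      if (nrow(members) > 0) modes[j, ] <- column_modes(members, ncat)
    }
  }
  d <- mode_distances(x, modes)
  labels <- max.col(-d, ties.method = "first")
  cost <- sum(d[cbind(seq_len(n), labels)])
  list(modes = modes, labels = labels, cost = cost, iterations = iter)
}

#' Fit a k-modes clustering to category patterns
#'
#' Huang-style alternating optimization on the matching dissimilarity:
#' assign every pattern to its nearest mode (ties to the lowest cluster
#' index), then update each mode attribute-wise to the most frequent
#' category among members (ties to the lowest category code), until no label
#' changes or `max_iter` is reached. The first start uses deterministic
#' density-based (Cao) initialization; the remaining `n_init - 1` starts use
#' distinct random patterns as initial modes. The best run by total cost is
#' kept, and everything is reproducible from `seed`.
#'
#' @param x Patterns: a [dedup_patterns()] result, a tibble of codes, or an
#'   integer matrix (rows = patterns).
#' @param k Number of clusters, at most the number of distinct patterns.
#' @param seed Integer seed controlling the random restarts.
#' @param n_init Number of starts (default 20).
#' @param max_iter Iteration cap per start (default 100).
#' @param init `"cao"` (default: Cao first, random restarts after) or
#'   `"random"` (all starts random).
#' @return An object of class `kmodes_fit`: list with `k`, `modes` (k x p
#'   integer matrix), `labels` (0-based cluster ids, one per input pattern),
#'   `cost` (total matching dissimilarity to assigned modes), `seed`,
#'   `n_init`, `iterations` (of the winning run), `init`.
#' @references Huang, Z. (1998) Extensions to the k-means algorithm for
#'   clustering large data sets with categorical values. Cao, F., Liang, J.,
#'   Bai, L. (2009) A new initialization method for categorical data
#'   clustering.
#' @export
#' @examples
#' pats <- simulate_patterns(K = 3, length = 6, n = 60, eps = 0, seed = 1)
#' fit <- kmodes(pats$patterns, k = 3, seed = 1)
#' fit$cost
kmodes <- function(x, k, seed = 1L, n_init = 20L, max_iter = 100L,
                   init = c("cao", "random")) {
  init <- match.arg(init)
  x <- as_pattern_matrix(x)
  if (nrow(x) == 0) stop("empty input", call. = FALSE)
  distinct_rows <- !duplicated(do.call(paste, c(as.data.frame(x), sep = "\r")))
  n_distinct <- sum(distinct_rows)
  if (k > n_distinct) {
    stop("k exceeds the number of distinct patterns", call. = FALSE)
  }
  ncat <- max(x) + 1L
  distinct_idx <- which(distinct_rows)

  best <- NULL
  withr::with_seed(seed, {
    for (run in seq_len(n_init)) {
      modes <- if (run == 1 && init == "cao") {
        cao_init(x, k)
      } else {
        x[sample(distinct_idx, k), , drop = FALSE]
      }
      res <- kmodes_single(x, modes, max_iter, ncat)
      if (is.null(best) || res$cost < best$cost) best <- res
    }
  })
  d <- mode_distances(x, best$modes)
  point_cost <- d[cbind(seq_len(nrow(x)), best$labels)]
  within <- vapply(seq_len(k), function(j) {
    sum(point_cost[best$labels == j])
  }, numeric(1))
  structure(
    list(
      k = k, modes = best$modes, labels = best$labels - 1L,
      cost = best$cost, within_cost = within, seed = seed, n_init = n_init,
      iterations = best$iterations, init = init
    ),
    class = "kmodes_fit"
  )
}

#' @export
print.kmodes_fit <- function(x, ...) {
  cat(sprintf(
    "<kmodes_fit> k=%d  cost=%d  n=%d patterns  (%d starts, seed %d)\n",
    x$k, x$cost, length(x$labels), x$n_init, x$seed
  ))
  invisible(x)
}

#' @describeIn kmodes per-cluster summary: `cluster` (0-based id), `size`,
#'   `within_cost` (matching dissimilarity of members to their mode).
#' @method tidy kmodes_fit
#' @export
tidy.kmodes_fit <- function(x, ...) {
  tibble::tibble(
    cluster = seq_len(x$k) - 1L,
    size = tabulate(x$labels + 1L, nbins = x$k),
    within_cost = x$within_cost
  )
}

#' @method glance kmodes_fit
#' @export
glance.kmodes_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, cost = x$cost, n = length(x$labels),
    n_init = x$n_init, iterations = x$iterations, seed = x$seed
  )
}

#' @method augment kmodes_fit
#' @export
augment.kmodes_fit <- function(x, data = NULL, ...) {
  if (is.null(data)) {
    return(tibble::tibble(.cluster = x$labels))
  }
  data <- tibble::as_tibble(data)
  if (nrow(data) != length(x$labels)) {
    stop("`data` does not match the fitted patterns", call. = FALSE)
  }
  dplyr::mutate(data, .cluster = x$labels)
}

#' Cost curve over k and elbow selection
#'
#' Fits k-modes for every `k` from 1 to `k_max` (each best of `n_init`
#' starts), records the cost curve, and picks the elbow as the `k` with the
#' maximum second difference of cost, `cost[k-1] - 2 cost[k] + cost[k+1]`.
#' The automatic choice can be overridden downstream (the pipeline accepts a
#' fixed `k` per dataset).
#'
#' @inheritParams kmodes
#' @param k_max Largest k to scan (default 25; capped at the number of
#'   distinct patterns).
#' @return An object of class `elbow_curve`: list with `curve` (tibble of
#'   `k`, `cost`), `chosen_k`, `method`, `seed`.
#' @export
#' @examples
#' pats <- simulate_patterns(K = 3, length = 8, n = 90, eps = 0.03, seed = 2)
#' elbow_select(pats$patterns, k_max = 6, seed = 2, n_init = 5)$chosen_k
elbow_select <- function(x, k_max = 25L, seed = 1L, n_init = 20L,
                         max_iter = 100L) {
  if (k_max < 2) stop("`k_max` must be at least 2", call. = FALSE)
  xm <- as_pattern_matrix(x)
  n_distinct <- sum(!duplicated(do.call(paste, c(as.data.frame(xm), sep = "\r"))))
  ks <- seq_len(min(k_max, n_distinct))
  costs <- vapply(ks, function(k) {
    kmodes(xm, k, seed = seed + k, n_init = n_init, max_iter = max_iter)$cost
  }, numeric(1))
  curve <- tibble::tibble(k = ks, cost = costs)
  # beyond the number of distinct patterns the cost cannot move, so the
  # curve is padded flat for knee detection (k_max still bounds the scan)
  padded <- c(costs, rep(costs[length(costs)], min(k_max, length(ks) + 1L) - length(ks)))
  if (length(padded) >= 3) {
    np <- length(padded)
    d2 <- padded[seq_len(np - 2)] - 2 * padded[seq(2, np - 1)] + padded[seq(3, np)]
    chosen <- which.max(d2) + 1L
  } else {
    chosen <- ks[length(ks)]
  }
  structure(
    list(
      curve = curve, chosen_k = chosen,
      method = "max_second_difference", seed = seed
    ),
    class = "elbow_curve"
  )
}

#' @export
print.elbow_curve <- function(x, ...) {
  cat(sprintf(
    "<elbow_curve> k = 1..%d, chosen_k = %d (%s)\n",
    max(x$curve$k), x$chosen_k, x$method
  ))
  invisible(x)
}

#' @rdname elbow_select
#' @param object An `elbow_curve`.
#' @param ... Unused.
#' @method autoplot elbow_curve
#' @export
autoplot.elbow_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$k, y = .data$cost)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(
      xintercept = object$chosen_k,
      linetype = "dashed", colour = "red"
    ) +
    ggplot2::labs(
      title = "k-modes cost curve",
      subtitle = sprintf("elbow at k = %d", object$chosen_k),
      x = "k", y = "cost (matching dissimilarity)"
    ) +
    ggplot2::theme_minimal()
}

#' Propagate cluster labels from unique patterns to all source records
#'
#' Every source record inherits the cluster of its unique pattern through the
#' deduplication back-map.
#'
#' @param model A [kmodes()] fit on the unique patterns of `unique_table`.
#' @param unique_table The [dedup_patterns()] result the model was fitted on.
#' @return A tibble: the source records' key columns plus `cluster`
#'   (0-based).
#' @export
assign_clusters <- function(model, unique_table) {
  stopifnot(inherits(model, "kmodes_fit"), inherits(unique_table, "unique_patterns"))
  if (length(model$labels) != nrow(unique_table$patterns)) {
    stop("model was not fitted on these unique patterns", call. = FALSE)
  }
  keys <- unique_table$keys
  dplyr::mutate(
    keys,
    cluster = model$labels[keys$pattern_id]
  )
}
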