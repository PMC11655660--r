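#' Condition-mean feature matrix
#'
#' Averages trials within each labelled condition (task x content x
#' demand) for every feature, the input to the low-dimensional
#' representational geometry. With the full design present this yields
#' 12 rows (3 tasks x 2 contents x 2 demands).
#'
#' @param x observations x features matrix or [signal_features].
#' @param labels data frame with `task`, `content`, `demand` (taken from
#'   `x` when it is a [signal_features]).
#' @return conditions x features matrix with `task_content_demand` row
#'   names.
#' @export
condition_means <- function(x, labels = NULL) {
  if (inherits(x, "signal_features")) {
    labels <- x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  f <- interaction(factor(labels$task, levels = intersect(task_levels(),
                                                          unique(labels$task))),
                   factor(labels$content,
                          levels = intersect(content_levels(),
                                             unique(labels$content))),
                   factor(labels$demand,
                          levels = intersect(demand_levels(),
                                             unique(labels$demand))),
                   sep = "_", lex.order = TRUE)
  counts <- table(f)
  if (any(counts == 0)) {
    stop_invalid("empty condition cell(s): %s",
                 paste(names(counts)[counts == 0], collapse = ", "))
  }
  rowsum(x, f, reorder = TRUE) / as.vector(counts[levels(f)])
}

#' Two-dimensional PCA embedding of condition means
#'
#' Projects the condition-mean rows onto the first two principal axes.
#' The embedding is centered (column means zero).
#'
#' @param means conditions x features matrix (>= 3 rows, >= 2 columns).
#' @return an `embedding`: list with `points` (conditions x 2),
#'   `labels` (condition names) and `var_explained` (fractions for the
#'   two components).
#' @export
embed_pca2 <- function(means) {
  means <- as.matrix(means)
  if (nrow(means) < 3) stop_invalid("need >= 3 conditions")
  if (ncol(means) < 2) stop_invalid("need >= 2 features")
  pc <- stats::prcomp(means, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot == 0) stop_invalid("condition means have rank 0 (all identical)")
  pts <- pc$x[, 1:2, drop = FALSE]
  if (ncol(pts) < 2) pts <- cbind(pts, 0)
  colnames(pts) <- c("pc1", "pc2")
  ve <- (pc$sdev^2 / tot)[1:2]
  ve[is.na(ve)] <- 0
  structure(list(points = pts, labels = rownames(means),
                 var_explained = ve),
            class = "embedding")
}

#' Procrustes alignment of one embedding to another
#'
#' Centers and rigidly rotates (full orthogonal group, reflections
#' included) the target onto the reference to minimize the summed
#' squared distance; no scaling component is applied. The rigid
#' transform preserves all within-embedding pairwise distances.
#'
#' @param reference,target `embedding` objects with identical labels.
#' @param scaling apply a scaling component (default `FALSE`).
#' @return list with `embedding` (the aligned target) and `disparity`
#'   (residual sum of squares against the centered reference).
#' @export
procrustes_align <- function(reference, target, scaling = FALSE) {
  stopifnot(inherits(reference, "embedding"), inherits(target, "embedding"))
  if (!identical(reference$labels, target$labels)) {
    stop_invalid("reference and target condition labels differ")
  }
  pr <- vegan::procrustes(reference$points, target$points,
                          scale = scaling, symmetric = FALSE)
  pts <- pr$Yrot
  dimnames(pts) <- dimnames(reference$points)
  aligned <- structure(list(points = pts, labels = target$labels,
                            var_explained = target$var_explained),
                       class = "embedding")
  list(embedding = aligned, disparity = pr$ss)
}

#' Align several embeddings and average them
#'
#' All embeddings are Procrustes-aligned (without scaling) to the first
#' one supplied, then averaged elementwise. The reference choice is
#' deterministic: pass the list ordered by sorted participant/task ID.
#'
#' @param embeddings list of `embedding` objects with shared labels.
#' @return the averaged `embedding`.
#' @export
average_aligned <- function(embeddings) {
  if (!length(embeddings)) stop_invalid("no embeddings supplied")
  ref <- embeddings[[1]]
  ref_centered <- structure(list(
    points = scale(ref$points, scale = FALSE)[, , drop = FALSE],
    labels = ref$labels, var_explained = ref$var_explained),
    class = "embedding")
  attr(ref_centered$points, "scaled:center") <- NULL
  acc <- ref_centered$points
  if (length(embeddings) > 1) {
    for (e in embeddings[-1]) {
      acc <- acc + procrustes_align(ref_centered, e)$embedding$points
    }
  }
  ve <- rowMeans(vapply(embeddings, function(e) e$var_explained, numeric(2)))
  structure(list(points = acc / length(embeddings), labels = ref$labels,
                 var_explained = ve),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %d conditions, var explained %.1f%% + %.1f%%\n",
              nrow(x$points), 100 * x$var_explained[1],
              100 * x$var_explained[2]))
  invisible(x)
}

#' Write embeddings as a tidy TSV
#'
#' @param embeddings named list of `embedding` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embedding_table <- function(embeddings, path) {
  rows <- lapply(names(embeddings), function(nm) {
    e <- embeddings[[nm]]
    data.frame(id = nm, condition = e$labels,
               pc1 = e$points[, 1], pc2 = e$points[, 2],
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
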