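# LD pruning, reference-panel PC projection, random-forest continental
# ancestry assignment, and KING-robust kinship exclusion.

#' Window-based LD pruning
#'
#' Sliding windows of `window` variants advancing by `step`; within each
#' window, pairs with squared correlation above `r2_threshold` are resolved
#' by removing the later variant in position order (deterministic given the
#' input order). Monomorphic variants are removed first with a warning.
#' Defaults mirror the common `--indep-pairwise 500 50 0.05` setting.
#'
#' @param dosages samples x variants numeric matrix (column names = ids)
#' @param window,step window size and step, in variants
#' @param r2_threshold maximum tolerated pairwise r^2
#' @return character vector of kept variant ids (column names), in order
#' @export
ld_prune <- function(dosages, window = 500L, step = 50L,
                     r2_threshold = 0.05) {
  assert_that(window >= step && step >= 1, "window must be >= step >= 1")
  assert_that(r2_threshold > 0 && r2_threshold < 1, "r2 threshold in (0,1)")
  ids <- colnames(dosages) %||% as.character(seq_len(ncol(dosages)))
  v <- apply(dosages, 2, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " monomorphic variant(s) removed before pruning",
            call. = FALSE)
  }
  keep <- v > 0
  idx <- which(keep)
  m <- length(idx)
  if (m == 0) return(character(0))
  alive <- rep(TRUE, m)
  start <- 1L
  repeat {
    end <- min(start + window - 1L, m)
    win <- which(alive[start:end]) + start - 1L
    if (length(win) >= 2) {
      r2 <- suppressWarnings(stats::cor(dosages[, idx[win], drop = FALSE]))^2
      repeat {
        changed <- FALSE
        k <- length(win)
        for (a in seq_len(k - 1L)) {
          if (!alive[win[a]]) next
          for (b in (a + 1L):k) {
            if (!alive[win[b]]) next
            if (!is.na(r2[a, b]) && r2[a, b] > r2_threshold) {
              alive[win[b]] <- FALSE   # drop the later variant
              changed <- TRUE
            }
          }
        }
        if (!changed) break
      }
    }
    if (end == m) break
    start <- start + step
  }
  ids[idx[alive]]
}

#' Project cohort samples onto reference-panel principal components
#'
#' The decomposition is fit on the reference panel only (centering and
#' scaling by reference statistics); cohort samples are mapped through the
#' fixed loadings and are never allowed to refit the axes.
#'
#' @param ref_dosages reference samples x variants matrix
#' @param cohort_dosages cohort samples x variants matrix (columns matched to
#'   the reference by name)
#' @param n_pcs number of components (default 10)
#' @return list: `ref_pcs`, `cohort_pcs`, `rotation`, `center`, `scale`,
#'   `variants`
#' @export
project_pcs <- function(ref_dosages, cohort_dosages, n_pcs = 10) {
  shared <- intersect(colnames(ref_dosages), colnames(cohort_dosages))
  if (length(shared) < 100)
    stop("fewer than 100 shared variants between reference and cohort",
         call. = FALSE)
  ref <- ref_dosages[, shared, drop = FALSE]
  v <- apply(ref, 2, stats::var)
  shared <- shared[v > 0]
  ref <- ref[, v > 0, drop = FALSE]
  pca <- stats::prcomp(ref, center = TRUE, scale. = TRUE)
  n_pcs <- min(n_pcs, ncol(pca$rotation))
  rot <- pca$rotation[, seq_len(n_pcs), drop = FALSE]
  # block-wise projection keeps memory flat for large cohorts
  n <- nrow(cohort_dosages)
  cohort_pcs <- matrix(NA_real_, n, n_pcs,
                       dimnames = list(rownames(cohort_dosages),
                                       colnames(rot)))
  blocks <- split(seq_len(n), ceiling(seq_len(n) / 20000))
  for (b in blocks) {
    x <- sweep(cohort_dosages[b, shared, drop = FALSE], 2, pca$center, "-")
    x <- sweep(x, 2, pca$scale, "/")
    cohort_pcs[b, ] <- x %*% rot
  }
  list(ref_pcs = pca$x[, seq_len(n_pcs), drop = FALSE],
       cohort_pcs = cohort_pcs,
       rotation = rot, center = pca$center, scale = pca$scale,
       variants = shared)
}

#' Random-forest continental ancestry assignment
#'
#' Trains a random forest (500 trees) on the labeled reference PCs, reports
#' held-out accuracy from an internal stratified split, then refits on the
#' full reference and predicts each cohort sample's ancestry with a class
#' probability. Samples whose top class probability falls below
#' `uncertain_below` are flagged.
#'
#' @param ref_pcs reference samples x PCs matrix
#' @param ref_labels ancestry labels for the reference rows
#' @param cohort_pcs cohort samples x PCs matrix
#' @param holdout_fraction fraction of the reference held out for accuracy
#' @param uncertain_below probability threshold for the `uncertain` flag
#' @param seed random-forest seed
#' @return list: `assignments` (data.frame with label, probability,
#'   uncertain), `holdout_accuracy`
#' @export
classify_ancestry <- function(ref_pcs, ref_labels, cohort_pcs,
                              holdout_fraction = 0.2, uncertain_below = 0.5,
                              seed = 1L) {
  ref_labels <- factor(ref_labels)
  if (any(table(ref_labels) == 0))
    stop("ancestry class absent from training reference", call. = FALSE)
  set.seed(seed)
  n <- nrow(ref_pcs)
  hold <- unlist(lapply(split(seq_len(n), ref_labels), function(ii) {
    sample(ii, max(1, round(length(ii) * holdout_fraction)))
  }))
  rf_train <- randomForest::randomForest(
    x = ref_pcs[-hold, , drop = FALSE], y = droplevels(ref_labels[-hold]),
    ntree = 500)
  pred_hold <- stats::predict(rf_train, ref_pcs[hold, , drop = FALSE])
  acc <- mean(as.character(pred_hold) == as.character(ref_labels[hold]))
  set.seed(seed)
  rf <- randomForest::randomForest(x = ref_pcs, y = ref_labels, ntree = 500)
  prob <- stats::predict(rf, cohort_pcs, type = "prob")
  lab <- colnames(prob)[max.col(prob, ties.method = "first")]
  pmax_ <- prob[cbind(seq_len(nrow(prob)), max.col(prob, ties.method = "first"))]
  list(assignments = data.frame(
         participant_id = rownames(cohort_pcs) %||% seq_len(nrow(cohort_pcs)),
         ancestry = lab, probability = pmax_,
         uncertain = pmax_ < uncertain_below,
         stringsAsFactors = FALSE),
       holdout_accuracy = acc)
}

#' KING-robust pairwise kinship
#'
#' The between-family moment estimator
#' \deqn{\hat{\phi}_{ij} = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{N_{Aa}^{(i)} + N_{Aa}^{(j)}}}
#' where \eqn{N_{Aa,Aa}} counts variants heterozygous in both samples,
#' \eqn{N_{AA,aa}} counts opposite homozygotes, and \eqn{N_{Aa}^{(\cdot)}}
#' counts heterozygous variants per sample. Robust to population structure;
#' ~0.5 for duplicates/MZ twins, ~0.25 for first-degree pairs, ~0 for
#' unrelateds. Computed for all pairs via indicator cross-products, so keep
#' the sample count to the scale kinship screening is actually run at.
#'
#' @param dosages samples x variants matrix of 0/1/2 dosages (pruned set)
#' @return data.frame: id1, id2, kinship (each unordered pair once)
#' @export
king_kinship <- function(dosages) {
  ids <- rownames(dosages) %||% as.character(seq_len(nrow(dosages)))
  H <- (dosages == 1) * 1
  A0 <- (dosages == 0) * 1
  A2 <- (dosages == 2) * 1
  n_hh <- H %*% t(H)
  n_opp <- A0 %*% t(A2) + A2 %*% t(A0)
  n_het <- rowSums(H)
  den <- outer(n_het, n_het, "+")
  phi <- (n_hh - 2 * n_opp) / den
  ut <- which(upper.tri(phi), arr.ind = TRUE)
  data.frame(id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
             kinship = phi[ut], stringsAsFactors = FALSE)
}

#' Greedy exclusion of related samples
#'
#' Drops samples until no retained pair exceeds the kinship threshold.
#' Deterministic: at each step the member of the most-connected offending
#' set with the most relatives is dropped, ties broken by lexicographic id.
#' Idempotent on its own output.
#'
#' @param kinship data.frame with id1, id2, kinship (from [king_kinship()])
#' @param ids full sample id vector (so unrelated samples are retained)
#' @param threshold kinship cutoff (default 0.0442, third-degree)
#' @return character vector of retained ids
#' @export
exclude_related <- function(kinship, ids, threshold = 0.0442) {
  drop <- character(0)
  edges <- kinship[kinship$kinship > threshold, c("id1", "id2"), drop = FALSE]
  while (nrow(edges) > 0) {
    deg <- sort(table(c(edges$id1, edges$id2)), decreasing = TRUE)
    top <- max(deg)
    victim <- sort(names(deg)[deg == top])[1]
    drop <- c(drop, victim)
    edges <- edges[edges$id1 != victim & edges$id2 != victim, , drop = FALSE]
  }
  setdiff(ids, drop)
}
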