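#' Build a ranked list from a named metric
#'
#' Orders genes by the metric, descending, with ties broken by gene id so the
#' ranking is deterministic. Used for PC loadings and for AUC / sensitivity
#' rankings of biomarkers.
#'
#' @param metric named numeric vector (names = gene/variable ids).
#' @param source tag recording what the metric is ("PC loading", "AUC", ...).
#' @return list of class `ranked_list`: `ids`, `metric` (descending), `source`.
#' @export
ranked_list <- function(metric, source = "metric") {
  ps_assert(!is.null(names(metric)) && !anyDuplicated(names(metric)),
            "metric must be named with unique ids")
  ps_assert(all(is.finite(metric)), "metric must be finite")
  ord <- order(-metric, names(metric))
  structure(list(ids = names(metric)[ord], metric = unname(metric[ord]),
                 source = source),
            class = "ranked_list")
}

# Core weighted Kolmogorov-Smirnov enrichment score from sorted hit
# positions. Hits increment the running sum by |metric|^p / sum over hits of
# |metric|^p; misses decrement by 1 / (N - |S|). ES is the signed extremum of
# the running sum. Candidate extrema occur only at hit positions (value after
# the hit step) and immediately before hit positions, which is what is
# evaluated here; the brute-force full running sum is kept in the test suite
# as the independent oracle.
es_from_positions <- function(stat_abs_p, pos, N) {
  k <- length(pos)
  if (k == N) {  # no miss steps: running sum climbs to exactly 1
    return(list(es = 1, extremum_hit = k))
  }
  w <- stat_abs_p[pos]
  NR <- sum(w)
  if (NR == 0) { # all hit weights zero: only miss steps matter
    w <- rep(1 / k, k); NR <- 1
  }
  hits_cum <- cumsum(w) / NR
  miss <- 1 / (N - k)
  at_hit <- hits_cum - (pos - seq_len(k)) * miss       # just after hit i
  before_hit <- c(0, hits_cum[-k]) - (pos - seq_len(k)) * miss # just before
  i_max <- which.max(at_hit)
  i_min <- which.min(before_hit)
  es_pos <- at_hit[i_max]
  es_neg <- before_hit[i_min]
  # exact-magnitude ties resolve to the positive extremum; the relative
  # tolerance keeps the choice stable across float summation orders
  if (es_pos >= abs(es_neg) - 1e-9 * (es_pos + abs(es_neg))) {
    list(es = es_pos, extremum_hit = i_max)
  } else {
    list(es = es_neg, extremum_hit = i_min)
  }
}

#' Weighted-KS enrichment score of one gene set
#'
#' @param ranked a [ranked_list()].
#' @param set character vector of member ids.
#' @param p weight exponent on |metric| (default 1, the GSEA convention).
#' @return list: `es`, `leading_edge` (hit ids at/before the extremum for
#'   positive ES, at/after it for negative ES), `running_sum` (full N-length
#'   running sum, for inspection), `hit_positions`.
#' @export
enrichment_score <- function(ranked, set, p = 1) {
  ps_assert(inherits(ranked, "ranked_list"), "ranked must be a ranked_list")
  N <- length(ranked$ids)
  pos <- sort(match(set, ranked$ids))
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0) ps_stop("empty intersection of set with ranked ids")
  stat_abs_p <- abs(ranked$metric)^p
  res <- es_from_positions(stat_abs_p, pos, N)
  k <- length(pos)
  hit_ids <- ranked$ids[pos]
  leading <- if (res$es >= 0) hit_ids[seq_len(res$extremum_hit)]
             else hit_ids[seq(res$extremum_hit, k)]
  # full running sum (O(N); used for plots and the oracle cross-check)
  inc <- rep(-if (k < N) 1 / (N - k) else 0, N)
  w <- stat_abs_p[pos]
  if (sum(w) == 0) w <- rep(1, k)
  inc[pos] <- w / sum(w)
  list(es = res$es, leading_edge = leading, running_sum = cumsum(inc),
       hit_positions = pos)
}

#' Preranked GSEA with a gene-sampling null
#'
#' For each gene set, computes the weighted-KS enrichment score on the ranked
#' list, then a permutation null by drawing random gene sets of the same size
#' from the ranked universe (nulls are shared across sets of equal size).
#' NES = ES / mean(|null ES| of matching sign); the p-value is two-sided with
#' add-one smoothing, p = (1 + #(|null| >= |ES|)) / (n_perm + 1), and is
#' BH-adjusted across tested sets. When a p-value sits at the smoothing floor
#' the permutation count escalates (x10 up to `max_perm`).
#'
#' @param ranked a [ranked_list()].
#' @param sets a [gene_set_collection()].
#' @param n_perm permutations per set size (default 10000).
#' @param min_size,max_size set-size bounds after intersection with the
#'   ranked universe (defaults 5 and 500); out-of-range sets are skipped and
#'   logged.
#' @param p weight exponent (default 1).
#' @param seed integer seed for the permutation stream.
#' @param max_perm escalation cap for the adaptive refinement (default 1e5).
#' @return data frame of class `enrichment_result`: pathway, size, es, nes,
#'   pval, padj, leading_edge (list column).
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 10000, min_size = 5,
                           max_size = 500, p = 1, seed = 1,
                           max_perm = 1e5) {
  ps_assert(n_perm >= 100, "n_perm must be >= 100")
  N <- length(ranked$ids)
  if (length(sets$sets) > 0) {
    ps_assert(max(lengths(sets$sets)) <= N,
              "ranked universe smaller than the largest gene set")
  }
  max_size <- min(max_size, N)
  stat_abs_p <- abs(ranked$metric)^p
  obs <- lapply(names(sets$sets), function(nm) {
    pos <- sort(match(sets$sets[[nm]], ranked$ids))
    pos <- pos[!is.na(pos)]
    list(name = nm, pos = pos, size = length(pos))
  })
  sizes <- vapply(obs, `[[`, 0L, "size")
  in_range <- sizes >= min_size & sizes <= max_size
  if (any(!in_range)) {
    ps_log(sprintf("gsea: %d set(s) outside size range [%d, %d] skipped",
                   sum(!in_range), min_size, max_size))
  }
  obs <- obs[in_range]
  if (length(obs) == 0) {
    return(structure(data.frame(pathway = character(), size = integer(),
                                es = numeric(), nes = numeric(),
                                pval = numeric(), padj = numeric()),
                     class = c("enrichment_result", "data.frame")))
  }
  null_es_for_size <- function(k, B, seed_k) {
    with_seed(seed_k, {
      vapply(seq_len(B), function(b) {
        pos <- sort(sample.int(N, k))
        es_from_positions(stat_abs_p, pos, N)$es
      }, 0)
    })
  }
  null_cache <- new.env(parent = emptyenv())
  get_null <- function(k, B) {
    key <- sprintf("k%d_B%d", k, B)
    if (!is.null(null_cache[[key]])) return(null_cache[[key]])
    null_cache[[key]] <- null_es_for_size(k, B, derive_seed(seed, key))
    null_cache[[key]]
  }
  rows <- lapply(obs, function(o) {
    sc <- enrichment_score(ranked, ranked$ids[o$pos], p = p)
    B <- n_perm
    repeat {
      null <- get_null(o$size, B)
      pv <- (1 + sum(abs(null) >= abs(sc$es))) / (B + 1)
      at_floor <- pv <= 1 / (B + 1) + 1e-12
      if (!at_floor || B >= max_perm) break
      B <- min(B * 10, max_perm)
    }
    same_sign <- if (sc$es >= 0) null[null >= 0] else null[null < 0]
    denom <- mean(abs(same_sign))
    nes <- if (is.finite(denom) && denom > 0) sc$es / denom else NA_real_
    data.frame(pathway = o$name, size = o$size, es = sc$es, nes = nes,
               pval = pv, leading_edge = I(list(sc$leading_edge)))
  })
  res <- do.call(rbind, rows)
  res$padj <- bh_adjust(res$pval)
  res <- res[, c("pathway", "size", "es", "nes", "pval", "padj",
                 "leading_edge")]
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Direction of change implied by enrichment and PC orientation
#'
#' A set enriched at one end of a PC-loading ranking changes in PE according
#' to the product of signs: genes loading with sign s on a PC whose score
#' correlates with PE with sign t move in PE with sign s * t. Hence
#' Upregulated iff sign(NES) * sign(r) > 0, Downregulated otherwise; a zero
#' input yields "n/a" with a warning.
#'
#' @param nes signed normalized enrichment score.
#' @param pc_condition_r signed PC-condition Pearson correlation.
#' @return "Upregulated", "Downregulated" or "n/a".
#' @export
infer_direction <- function(nes, pc_condition_r) {
  if (!is.finite(nes) || !is.finite(pc_condition_r) ||
      nes == 0 || pc_condition_r == 0) {
    warning("zero or non-finite input: direction is n/a", call. = FALSE)
    return("n/a")
  }
  if (sign(nes) * sign(pc_condition_r) > 0) "Upregulated" else "Downregulated"
}

#' Z-score heatmap matrix for an enriched set
#'
#' Per-gene Z-scores across samples, with rows ordered by the genes' loadings
#' on the chosen PC and columns by the samples' scores on that PC, matching
#' the conventional enriched-pathway heatmap layout. Constant genes get a row
#' of zeros and a flag.
#'
#' @param expr normalized expression matrix, genes x samples.
#' @param genes member ids to display (must be rows of `expr`).
#' @param pca a `pca_result` over (a superset of) these genes/samples.
#' @param pc PC name, e.g. "PC1".
#' @param leading_edge optional ids flagged as leading genes.
#' @return list: `z` (ordered matrix), `constant` (flag per row),
#'   `leading` (flag per row).
#' @export
zscore_matrix <- function(expr, genes, pca, pc, leading_edge = character()) {
  ps_assert(all(genes %in% rownames(expr)), "genes missing from expr")
  ps_assert(pc %in% colnames(pca$loadings), "unknown PC: ", pc)
  x <- expr[genes, , drop = FALSE]
  sds <- matrixStats::rowSds(x)
  z <- (x - rowMeans(x)) / ifelse(sds > 0, sds, 1)
  z[sds == 0, ] <- 0
  row_ord <- order(pca$loadings[genes, pc], decreasing = TRUE)
  col_ord <- order(pca$scores[colnames(expr), pc], decreasing = TRUE)
  z <- z[row_ord, col_ord, drop = FALSE]
  list(z = z,
       constant = stats::setNames(sds[row_ord] == 0, rownames(z)),
       leading = stats::setNames(rownames(z) %in% leading_edge, rownames(z)))
}
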