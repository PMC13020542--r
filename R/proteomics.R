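#' Per-subject pre/post expression change
#'
#' Computes `post - pre` per subject per protein in NPX (log2) units, so a
#' change of +1 corresponds to a doubling of protein concentration.
#'
#' @param npx An `npx_matrix` (from [simulate_npx()]) or a plain proteins x
#'   samples matrix; in the latter case `annotation` must be supplied.
#' @param annotation Sample annotation data frame with `sample`, `subject`,
#'   `timepoint` (`"pre"`/`"post"`) when `npx` is a plain matrix.
#' @return A subjects x proteins numeric matrix of changes.
#' @export
pairwise_change <- function(npx, annotation = NULL) {
  if (inherits(npx, "npx_matrix")) {
    annotation <- npx$annotation
    npx <- npx$npx
  }
  stopifnot(is.matrix(npx), !is.null(annotation))
  ann <- annotation[match(colnames(npx), annotation$sample), ]
  pre <- ann$subject[ann$timepoint == "pre"]
  post <- ann$subject[ann$timepoint == "post"]
  unmatched <- union(setdiff(pre, post), setdiff(post, pre))
  if (length(unmatched)) {
    stop("subjects without matched pre/post samples: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  subjects <- unique(ann$subject)
  chg <- vapply(subjects, function(s) {
    post_col <- which(ann$subject == s & ann$timepoint == "post")[1L]
    pre_col <- which(ann$subject == s & ann$timepoint == "pre")[1L]
    npx[, post_col] - npx[, pre_col]
  }, numeric(nrow(npx)))
  t(chg)  # subjects x proteins
}

#' Per-protein two-group Student's t-test with retention threshold
#'
#' Tests each protein between two groups (unpaired by default, matching a
#' strong-vs-weak responder comparison) or against zero change (paired /
#' one-sample mode). Proteins with `p < threshold` are retained; no
#' multiplicity correction is applied by default. Zero-variance proteins get
#' `p = 1` when group means are equal and `p = 0` (retained) when they
#' differ.
#'
#' @param changes Subjects x proteins matrix (e.g. from
#'   [pairwise_change()]).
#' @param group Length-`nrow(changes)` factor/vector with two levels for the
#'   unpaired test; `NULL` for the one-sample (paired-change) test against 0.
#' @param threshold Retention P-value cut-off (default 0.05).
#' @param fdr If TRUE, retain by Benjamini-Hochberg adjusted P instead
#'   (off by default, matching the unadjusted workflow).
#' @return Data frame with one row per protein: `protein`, group means,
#'   `difference`, `p_value`, `retained`.
#' @export
de_ttest <- function(changes, group = NULL, threshold = 0.05, fdr = FALSE) {
  stopifnot(is.matrix(changes))
  proteins <- colnames(changes)
  if (is.null(proteins)) proteins <- sprintf("P%03d", seq_len(ncol(changes)))
  if (is.null(group)) {
    res <- apply(changes, 2L, function(x) {
      if (length(x) < 2L) stop("need >= 2 observations", call. = FALSE)
      m <- mean(x)
      if (stats::sd(x) == 0) {
        p <- if (m == 0) 1 else 0
      } else {
        p <- stats::t.test(x)$p.value
      }
      c(mean_a = m, mean_b = 0, difference = m, p_value = p)
    })
  } else {
    g <- factor(group)
    stopifnot(length(g) == nrow(changes))
    if (nlevels(g) != 2L) {
      stop("`group` must have exactly two levels", call. = FALSE)
    }
    if (min(table(g)) < 2L) stop("need >= 2 observations per group", call. = FALSE)
    res <- apply(changes, 2L, function(x) {
      xa <- x[g == levels(g)[1L]]
      xb <- x[g == levels(g)[2L]]
      ma <- mean(xa); mb <- mean(xb)
      if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
        p <- if (ma == mb) 1 else 0
      } else {
        p <- stats::t.test(xa, xb, var.equal = FALSE)$p.value
      }
      c(mean_a = ma, mean_b = mb, difference = ma - mb, p_value = p)
    })
  }
  out <- as.data.frame(t(res))
  out <- cbind(protein = proteins, out)
  rownames(out) <- NULL
  p_use <- if (fdr) stats::p.adjust(out$p_value, "BH") else out$p_value
  out$retained <- p_use < threshold
  out
}

#' Split subjects into strong and weak FMD responders
#'
#' Ranks subjects by their noise-induced FMD change. The `n` subjects with
#' the lowest changes (strongest noise-induced FMD impairment) form the
#' "strong" responder group; the `n` with the highest changes form the
#' "weak" group. Ties are broken deterministically by subject order.
#'
#' @param fmd_changes Named numeric vector of per-subject FMD changes, %.
#' @param n Group size (default 20; requires at least `2n` subjects).
#' @return A `responder_split`: list with `strong`, `weak` (subject id
#'   vectors) and `ranking` (the sorted data frame).
#' @export
split_responders <- function(fmd_changes, n = 20L) {
  subjects <- names(fmd_changes)
  if (is.null(subjects)) subjects <- sprintf("S%02d", seq_along(fmd_changes))
  if (length(fmd_changes) < 2L * n) {
    stop("need at least ", 2L * n, " subjects for a ", n, "/", n, " split (got ",
         length(fmd_changes), ")", call. = FALSE)
  }
  ord <- order(fmd_changes, seq_along(fmd_changes))  # ties: subject order
  ranking <- data.frame(subject = subjects[ord],
                        fmd_change = unname(fmd_changes[ord]))
  strong <- ranking$subject[seq_len(n)]
  weak <- ranking$subject[seq(nrow(ranking) - n + 1L, nrow(ranking))]
  structure(list(strong = strong, weak = weak, ranking = ranking, n = n),
            class = "responder_split")
}

#' Z-normalized group means with Euclidean hierarchical clustering
#'
#' Computes the per-group mean change for every protein, z-normalizes each
#' protein row across groups (mean 0, sd 1), and clusters proteins by
#' Euclidean distance with agglomerative linkage, returning the heat-map row
#' order.
#'
#' @param changes Subjects x proteins matrix of retained-protein changes.
#' @param group Length-`nrow(changes)` grouping vector (e.g. strong/weak).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return List with `z` (proteins x groups z-normalized mean matrix, rows
#'   in leaf order), `order` (protein ids in leaf order), `hclust` (the tree,
#'   `NULL` for a single protein) and `note`.
#' @export
zscore_cluster <- function(changes, group, linkage = "average") {
  stopifnot(is.matrix(changes), length(group) == nrow(changes))
  g <- factor(group)
  m <- matrix(NA_real_, nrow = ncol(changes), ncol = nlevels(g),
              dimnames = list(colnames(changes), levels(g)))
  for (lv in levels(g)) {
    m[, lv] <- colMeans(changes[g == lv, , drop = FALSE])
  }
  z <- t(apply(m, 1L, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  dimnames(z) <- dimnames(m)
  if (nrow(z) < 2L) {
    return(list(z = z, order = rownames(z), hclust = NULL,
                note = "single protein: returned unclustered"))
  }
  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = linkage)
  ord <- hc$order
  list(z = z[ord, , drop = FALSE], order = rownames(z)[ord], hclust = hc,
       note = NULL)
}

#' Principal-component scores of protein changes
#'
#' Centred (unscaled) PCA of the subjects x proteins change matrix.
#'
#' @param changes Subjects x proteins matrix.
#' @param k Number of components to return (default 2, capped at the rank).
#' @return List with `scores` (subjects x k), `explained` (variance
#'   fractions per returned component), `note` (set when the matrix is rank
#'   degenerate).
#' @export
pca_scores <- function(changes, k = 2L) {
  stopifnot(is.matrix(changes))
  if (nrow(changes) < 2L || ncol(changes) < 2L) {
    stop("need >= 2 subjects and >= 2 proteins", call. = FALSE)
  }
  pc <- stats::prcomp(changes, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  total <- sum(ev)
  note <- NULL
  rank <- sum(ev > max(ev) * 1e-12)
  if (rank < min(dim(changes))) {
    note <- sprintf("rank-degenerate change matrix (rank %d)", rank)
  }
  k <- min(k, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = ev[seq_len(k)] / total,
       note = note)
}

#' Filter a protein-interaction edge list by confidence score
#'
#' Keeps edges with interaction score strictly greater than `min_score`
#' (default 0.4) between proteins in `node_set`, and reports connected
#' components of the resulting subgraph.
#'
#' @param edges Data frame with columns `node_a`, `node_b`, `score` (scores
#'   in `[0, 1]`), or a path to a TSV with those columns.
#' @param min_score Strict lower bound on the interaction score.
#' @param node_set Proteins to keep (default: all nodes in `edges`).
#' @return List with `edges` (the retained edge data frame), `graph` (an
#'   igraph object) and `components` (data frame `node`, `component`).
#' @export
filter_network <- function(edges, min_score = 0.4, node_set = NULL) {
  if (is.character(edges)) {
    edges <- utils::read.delim(edges, stringsAsFactors = FALSE)
  }
  need <- c("node_a", "node_b", "score")
  if (!all(need %in% names(edges))) {
    stop("edge list must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(edges$score))
  if (anyNA(score)) {
    stop("malformed edge row(s): non-numeric score at row ",
         which(is.na(score))[1L], call. = FALSE)
  }
  if (any(score < 0 | score > 1)) {
    stop("interaction scores must lie in [0, 1]", call. = FALSE)
  }
  keep <- score > min_score
  if (!is.null(node_set)) {
    keep <- keep & edges$node_a %in% node_set & edges$node_b %in% node_set
  }
  sub <- edges[keep, need]
  rownames(sub) <- NULL
  g <- igraph::graph_from_data_frame(sub[, c("node_a", "node_b")],
                                     directed = FALSE)
  comp <- if (igraph::vcount(g) > 0) {
    cc <- igraph::components(g)
    data.frame(node = names(cc$membership),
               component = as.integer(cc$membership))
  } else {
    data.frame(node = character(0), component = integer(0))
  }
  list(edges = sub, graph = g, components = comp)
}

#' Run the responder-stratification proteomics workflow
#'
#' Pairwise pre/post changes, strong/weak responder split by FMD change,
#' per-protein unpaired t-tests between responder groups, z-normalized
#' clustering of retained proteins, PCA of changes, and (optionally)
#' score-filtered interaction subnetwork of retained proteins.
#'
#' @param npx An `npx_matrix`.
#' @param fmd_changes Named per-subject FMD changes (defaults to the
#'   annotation carried by `npx`).
#' @param split_n Responder group size (default 20).
#' @param p_threshold Retention threshold (default 0.05; the looser 0.1 used
#'   for network display is available here).
#' @param edges Optional interaction edge list (data frame or TSV path).
#' @param min_score Interaction-score cut-off (default 0.4, strict).
#' @return List with `changes`, `split`, `de`, `cluster`, `pca`, `network`.
#' @export
run_proteomics <- function(npx, fmd_changes = NULL, split_n = 20L,
                           p_threshold = 0.05, edges = NULL, min_score = 0.4) {
  stopifnot(inherits(npx, "npx_matrix"))
  if (is.null(fmd_changes)) {
    ann <- npx$annotation[npx$annotation$timepoint == "pre", ]
    fmd_changes <- stats::setNames(ann$fmd_change, ann$subject)
  }
  changes <- pairwise_change(npx)
  split <- split_responders(fmd_changes, n = split_n)
  used <- c(split$strong, split$weak)
  chg_used <- changes[used, , drop = FALSE]
  grp <- factor(ifelse(used %in% split$strong, "strong", "weak"),
                levels = c("strong", "weak"))
  de <- de_ttest(chg_used, group = grp, threshold = p_threshold)
  retained <- de$protein[de$retained]
  cluster <- if (length(retained) >= 1L) {
    zscore_cluster(chg_used[, retained, drop = FALSE], grp)
  } else NULL
  pca <- pca_scores(chg_used)
  network <- if (!is.null(edges)) {
    filter_network(edges, min_score = min_score, node_set = retained)
  } else NULL
  list(changes = changes, split = split, de = de, cluster = cluster,
       pca = pca, network = network, group = grp)
}
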