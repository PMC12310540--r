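# Mutation-landscape analyses: summaries, pairwise associations,
# Benjamini-Hochberg correction, Bayesian-network structure learning,
# hierarchical clustering of genes.

#' Summarise the mutation landscape
#'
#' Computes the per-category mutated-patient counts, the distribution of the
#' number of additional (non-driver) mutations per patient, and per-category
#' "isolated" fractions (patients mutated in a category's gene and in no
#' other gene). Percentages are over all patients and reported to one
#' decimal.
#'
#' @param matrix A `mutation_matrix` from [build_mutation_matrix()].
#' @param variants Optional prognostic variant subset; if supplied, the
#'   summary also reports the fraction of patients carrying multiple variants
#'   of the same gene (per gene).
#' @return List with components `n_patients`, `category_counts`,
#'   `n_additional_distribution` (count and pct for 0, 1, 2, >=3 and the
#'   `>=1` / `>=2` aggregates), `isolated` (per gene: mutated count, isolated
#'   count, pct of mutated) and, when `variants` is given, `multi_variant`
#'   (per gene: patients with >=2 variants of that gene, pct of cohort).
#' @export
summarize_landscape <- function(matrix, variants = NULL) {
  n <- length(matrix$patients)
  pct <- function(x, denom = n) if (denom > 0) round(100 * x / denom, 1) else x * 0

  counts <- colSums(matrix$presence)
  category_counts <- data.frame(
    category = matrix$categories,
    n_mutated = as.integer(counts),
    pct = pct(as.integer(counts)),
    row.names = NULL)

  na <- matrix$n_additional
  dist <- data.frame(
    n_additional = c("0", "1", "2", ">=3", ">=1", ">=2"),
    count = c(sum(na == 0), sum(na == 1), sum(na == 2), sum(na >= 3),
              sum(na >= 1), sum(na >= 2)),
    row.names = NULL)
  dist$pct <- pct(dist$count)

  genes <- unique(category_gene(matrix$categories))
  if (length(genes)) {
    gene_presence <- vapply(genes, function(g) {
      cols <- matrix$categories[category_gene(matrix$categories) == g]
      as.integer(rowSums(matrix$presence[, cols, drop = FALSE]) > 0)
    }, integer(n))
    gene_presence <- base::matrix(gene_presence, nrow = n,
                                  dimnames = list(NULL, genes))
    isolated <- data.frame(
      gene = genes,
      n_mutated = as.integer(colSums(gene_presence)),
      n_isolated = vapply(seq_along(genes), function(j) {
        sum(gene_presence[, j] == 1 &
              rowSums(gene_presence[, -j, drop = FALSE]) == 0)
      }, integer(1)),
      row.names = NULL)
    isolated$pct_of_mutated <- ifelse(isolated$n_mutated > 0,
                                      round(100 * isolated$n_isolated / isolated$n_mutated, 1),
                                      NA)
  } else {
    isolated <- data.frame(gene = character(0), n_mutated = integer(0),
                           n_isolated = integer(0), pct_of_mutated = numeric(0))
  }

  out <- list(n_patients = n, category_counts = category_counts,
              n_additional_distribution = dist, isolated = isolated)

  if (!is.null(variants)) {
    nd <- variants[variants$is_driver != 1L, , drop = FALSE]
    tab <- table(nd$patient_id, nd$gene)
    multi <- vapply(genes, function(g)
      if (g %in% colnames(tab)) sum(tab[, g] >= 2) else 0L, numeric(1))
    out$multi_variant <- data.frame(gene = genes,
                                    n_patients_multi = as.integer(multi),
                                    pct = pct(as.integer(multi)),
                                    row.names = NULL)
  }
  out
}

#' Summarise CNV calls
#'
#' Per-region counts and percentages of patients carrying each copy-number
#' abnormality, plus the fraction with any non-chromosome-9 CNV. The
#' denominator defaults to the full patient list but can be restricted to
#' patients with evaluable CNV data.
#'
#' @param cnv Validated CNV data frame.
#' @param patients Patient identifiers forming the denominator.
#' @return Data frame of region, kind, count and pct, with an `any_non9`
#'   summary row.
#' @export
summarize_cnv <- function(cnv, patients) {
  n <- length(patients)
  cnv <- cnv[cnv$patient_id %in% patients, , drop = FALSE]
  per <- if (nrow(cnv)) {
    stats::aggregate(list(count = cnv$patient_id),
                     by = list(region = cnv$region, kind = cnv$kind),
                     FUN = function(x) length(unique(x)))
  } else data.frame(region = character(0), kind = character(0),
                    count = integer(0))
  non9 <- length(unique(cnv$patient_id[cnv$region != "9p"]))
  out <- rbind(per,
               data.frame(region = "any_non9", kind = "any", count = non9))
  out$pct <- if (n > 0) round(100 * out$count / n, 1) else 0
  out
}

#' Pairwise feature associations with BH correction
#'
#' Tests every pair of features across two blocks: binary-by-binary pairs use
#' the two-sided exact test on the 2x2 table (odds-ratio estimate);
#' binary-by-continuous pairs use the two-sided Wilcoxon rank-sum test with
#' direction from the median shift; continuous-by-continuous pairs use
#' Spearman rank correlation. Missing continuous values are handled
#' pairwise-complete. q-values come from Benjamini-Hochberg over the whole
#' table; `reported` flags rows at p < 0.05 to mirror a figure-style display.
#' A degenerate margin (constant column) yields a flagged row with estimate
#' `NA` and p = 1.
#'
#' @param binary Data frame / matrix of 0-1 features (patients in rows).
#' @param continuous Data frame / matrix of numeric features, same rows.
#' @return An association table: feature_a, feature_b, statistic_kind,
#'   estimate, p_value, q_value, direction, degenerate, reported.
#' @export
pairwise_association <- function(binary = NULL, continuous = NULL) {
  binary <- if (is.null(binary)) matrix(0, 0, 0) else as.matrix(binary)
  continuous <- if (is.null(continuous)) matrix(0, 0, 0) else as.matrix(continuous)
  rows <- list()
  add <- function(a, b, kind, est, p, dir, degen = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      feature_a = a, feature_b = b, statistic_kind = kind,
      estimate = est, p_value = p, direction = dir, degenerate = degen,
      stringsAsFactors = FALSE)
  }

  bn <- colnames(binary); cn <- colnames(continuous)
  # binary x binary
  if (ncol(binary) >= 2) {
    for (i in seq_len(ncol(binary) - 1)) for (j in seq(i + 1, ncol(binary))) {
      x <- binary[, i]; y <- binary[, j]
      ok <- !is.na(x) & !is.na(y); x <- x[ok]; y <- y[ok]
      if (length(unique(x)) < 2 || length(unique(y)) < 2) {
        add(bn[i], bn[j], "odds_ratio", NA_real_, 1, NA_character_, TRUE)
      } else {
        tab <- table(factor(x, 0:1), factor(y, 0:1))
        ft <- stats::fisher.test(tab)
        add(bn[i], bn[j], "odds_ratio", unname(ft$estimate), ft$p.value,
            if (ft$estimate > 1) "positive" else "negative")
      }
    }
  }
  # binary x continuous
  if (ncol(binary) >= 1 && ncol(continuous) >= 1) {
    for (i in seq_len(ncol(binary))) for (j in seq_len(ncol(continuous))) {
      x <- binary[, i]; y <- continuous[, j]
      ok <- !is.na(x) & !is.na(y); x <- x[ok]; y <- y[ok]
      if (length(unique(x)) < 2 || length(unique(y[!is.na(y)])) < 1 ||
          !any(x == 1) || !any(x == 0)) {
        add(bn[i], cn[j], "mean_shift", NA_real_, 1, NA_character_, TRUE)
      } else {
        shift <- stats::median(y[x == 1]) - stats::median(y[x == 0])
        if (length(unique(y)) < 2) {
          add(bn[i], cn[j], "mean_shift", 0, 1, NA_character_)
        } else {
          wt <- suppressWarnings(stats::wilcox.test(y[x == 1], y[x == 0]))
          add(bn[i], cn[j], "mean_shift", shift, wt$p.value,
              if (shift > 0) "positive" else if (shift < 0) "negative" else NA_character_)
        }
      }
    }
  }
  # continuous x continuous
  if (ncol(continuous) >= 2) {
    for (i in seq_len(ncol(continuous) - 1)) for (j in seq(i + 1, ncol(continuous))) {
      x <- continuous[, i]; y <- continuous[, j]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3 || length(unique(x[ok])) < 2 || length(unique(y[ok])) < 2) {
        add(cn[i], cn[j], "rank_correlation", NA_real_, 1, NA_character_, TRUE)
      } else {
        ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman"))
        add(cn[i], cn[j], "rank_correlation", unname(ct$estimate), ct$p.value,
            if (ct$estimate > 0) "positive" else "negative")
      }
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_a = character(0), feature_b = character(0),
               statistic_kind = character(0), estimate = numeric(0),
               p_value = numeric(0), direction = character(0),
               degenerate = logical(0))
  out$q_value <- bh_adjust(out$p_value)
  out$reported <- out$p_value < 0.05
  out[, c("feature_a", "feature_b", "statistic_kind", "estimate",
          "p_value", "q_value", "direction", "degenerate", "reported")]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns q-values by the step-up false-discovery-rate procedure:
#' q(i) = min over j >= i of p(j) * m / j on the sorted p-values, mapped back
#' to input order and capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0,1\].
#' @return Numeric vector of q-values, same order as input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0,1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

## --- Bayesian network structure learning (BIC hill-climbing) ---------------

# Family BIC for a Bernoulli node given its parent set: maximised tabular
# log-likelihood minus 0.5 * log(n) per free parameter (one per parent
# configuration).
family_bic <- function(x, parents_data, n) {
  if (is.null(parents_data) || NCOL(parents_data) == 0) {
    idx <- rep(1L, length(x)); n_cfg <- 1L
  } else {
    pm <- as.matrix(parents_data)
    idx <- as.integer(pm %*% 2^(seq_len(ncol(pm)) - 1)) + 1L
    n_cfg <- 2L^ncol(pm)
  }
  m <- tabulate(idx, n_cfg)
  m1 <- vapply(seq_len(n_cfg), function(k) sum(x[idx == k]), numeric(1))
  ll <- 0
  for (k in seq_len(n_cfg)) {
    if (m[k] == 0) next
    p <- m1[k] / m[k]
    if (p > 0) ll <- ll + m1[k] * log(p)
    if (p < 1) ll <- ll + (m[k] - m1[k]) * log(1 - p)
  }
  ll - 0.5 * log(n) * n_cfg
}

bic_score <- function(data, adj) {
  n <- nrow(data)
  sum(vapply(seq_len(ncol(data)), function(j) {
    pa <- which(adj[, j] == 1L)
    family_bic(data[, j], data[, pa, drop = FALSE], n)
  }, numeric(1)))
}

# Reachability check: TRUE if a path from -> to exists in adj.
has_path <- function(adj, from, to) {
  seen <- logical(ncol(adj)); frontier <- from
  while (length(frontier)) {
    seen[frontier] <- TRUE
    nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] == 1L))))
    frontier <- nxt[!seen[nxt]]
  }
  seen[to]
}

hill_climb <- function(data, start_adj = NULL) {
  p <- ncol(data); labs <- colnames(data); n <- nrow(data)
  adj <- if (is.null(start_adj)) matrix(0L, p, p, dimnames = list(labs, labs)) else start_adj
  fam <- vapply(seq_len(p), function(j)
    family_bic(data[, j], data[, which(adj[, j] == 1L), drop = FALSE], n),
    numeric(1))

  repeat {
    best <- list(delta = 1e-9, key = NULL)
    consider <- function(delta, key, apply_fun) {
      # strictly better, or equal-score tie broken by lexicographic move key
      if (delta > best$delta + 1e-9 ||
          (abs(delta - best$delta) <= 1e-9 && !is.null(best$key) &&
             key < best$key)) {
        best <<- list(delta = delta, key = key, apply_fun = apply_fun)
      }
    }
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i == j) next
      if (adj[i, j] == 0L) {                          # add i -> j
        if (adj[j, i] == 1L || has_path(adj, j, i)) next
        newfam <- family_bic(data[, j],
                             data[, c(which(adj[, j] == 1L), i), drop = FALSE], n)
        consider(newfam - fam[j], paste0("add:", labs[i], "->", labs[j]),
                 local({ ii <- i; jj <- j; nf <- newfam
                 function() { adj[ii, jj] <<- 1L; fam[jj] <<- nf } }))
      } else {                                        # delete i -> j
        pa <- setdiff(which(adj[, j] == 1L), i)
        newfam <- family_bic(data[, j], data[, pa, drop = FALSE], n)
        consider(newfam - fam[j], paste0("del:", labs[i], "->", labs[j]),
                 local({ ii <- i; jj <- j; nf <- newfam
                 function() { adj[ii, jj] <<- 0L; fam[jj] <<- nf } }))
        # reverse i -> j  (becomes j -> i)
        adj2 <- adj; adj2[i, j] <- 0L
        if (!has_path(adj2, i, j)) {
          newfam_j <- newfam
          newfam_i <- family_bic(data[, i],
                                 data[, c(which(adj[, i] == 1L), j), drop = FALSE], n)
          consider((newfam_j - fam[j]) + (newfam_i - fam[i]),
                   paste0("rev:", labs[i], "->", labs[j]),
                   local({ ii <- i; jj <- j; nfj <- newfam_j; nfi <- newfam_i
                   function() { adj[ii, jj] <<- 0L; adj[jj, ii] <<- 1L
                   fam[jj] <<- nfj; fam[ii] <<- nfi } }))
        }
      }
    }
    if (is.null(best$key)) break
    best$apply_fun()
  }
  list(adj = adj, score = sum(fam))
}

hill_climb_restarts <- function(data, n_restarts = 5L, n_perturb = 2L) {
  fit <- hill_climb(data)
  p <- ncol(data)
  if (p >= 2) for (r in seq_len(n_restarts)) {
    adj <- fit$adj
    for (k in seq_len(n_perturb)) {   # random legal edge flip
      i <- sample.int(p, 1); j <- sample.int(p, 1)
      if (i == j) next
      if (adj[i, j] == 1L) adj[i, j] <- 0L
      else if (adj[j, i] == 0L && !has_path(adj, j, i)) adj[i, j] <- 1L
    }
    cand <- hill_climb(data, start_adj = adj)
    if (cand$score > fit$score + 1e-9) fit <- cand
  }
  fit
}

#' Learn a mutation co-occurrence Bayesian network
#'
#' Greedy BIC hill-climbing over single-edge additions, deletions and
#' reversals for Bernoulli nodes with tabular conditional distributions,
#' starting from the empty graph with seeded random restarts. Edge
#' confidence is the fraction of nonparametric bootstrap resamples whose
#' learned structure contains the edge in its skeleton (direction ignored).
#' Only categories mutated in at least `min_patients` patients enter the
#' analysis. Deterministic given `seed`.
#'
#' @param matrix A `mutation_matrix` (its binary `presence` table is used),
#'   or a 0/1 matrix with column names.
#' @param min_patients Minimum mutated-patient count for a category to enter.
#' @param n_boot Number of bootstrap resamples for edge confidence.
#' @param seed Integer seed (required).
#' @param n_restarts Random restarts per hill-climb.
#' @return Object of class `gene_network`: list with `nodes`, `edges` (data
#'   frame from, to, confidence), `adjacency`, `score` (BIC of the selected
#'   structure) and `skeleton_confidence` (symmetric matrix).
#' @export
learn_network <- function(matrix, min_patients = 7L, n_boot = 100L, seed,
                          n_restarts = 5L) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  presence <- if (inherits(matrix, "mutation_matrix")) matrix$presence else as.matrix(matrix)
  keep <- colSums(presence) >= min_patients
  presence <- presence[, keep, drop = FALSE]
  presence <- presence[, order(colnames(presence)), drop = FALSE]
  p <- ncol(presence)
  empty_net <- function(score = NA_real_) {
    structure(list(nodes = colnames(presence),
                   edges = data.frame(from = character(0), to = character(0),
                                      confidence = numeric(0)),
                   adjacency = matrix(0L, p, p,
                                      dimnames = list(colnames(presence), colnames(presence))),
                   score = score,
                   skeleton_confidence = matrix(0, p, p,
                                                dimnames = list(colnames(presence), colnames(presence)))),
              class = "gene_network")
  }
  if (p < 2) {
    warning("fewer than 2 qualifying gene categories; returning empty network",
            call. = FALSE)
    return(empty_net())
  }

  set.seed(seed)
  fit <- hill_climb_restarts(presence, n_restarts = n_restarts)

  skel_conf <- matrix(0, p, p, dimnames = dimnames(fit$adj))
  n <- nrow(presence)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    bfit <- hill_climb_restarts(presence[idx, , drop = FALSE],
                                n_restarts = n_restarts)
    skel <- (bfit$adj + t(bfit$adj)) > 0
    skel_conf <- skel_conf + skel
  }
  skel_conf <- skel_conf / max(n_boot, 1L)

  idx <- which(fit$adj == 1L, arr.ind = TRUE)
  edges <- data.frame(
    from = colnames(presence)[idx[, 1]],
    to = colnames(presence)[idx[, 2]],
    confidence = skel_conf[idx],
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = colnames(presence), edges = edges,
                 adjacency = fit$adj, score = fit$score,
                 skeleton_confidence = skel_conf),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (BIC", format(x$score, digits = 6), ")\n")
  if (nrow(x$edges)) print(x$edges)
  invisible(x)
}

#' Hierarchical clustering of gene categories
#'
#' Agglomerative (average-linkage) clustering of gene categories on the
#' distance 1 - |Spearman correlation| between their VAF profiles across
#' patients. A constant column has distance 1 to every other category and is
#' flagged. Columns are processed in lexicographic order so ties break
#' deterministically.
#'
#' @param matrix A `mutation_matrix` (uses `max_vaf`) or a numeric matrix
#'   with named columns.
#' @param k Number of flat clusters to cut (default: mid-tree cut at half
#'   the maximum merge height).
#' @return List with `hclust` (the dendrogram), `distance`, `clusters`
#'   (named integer vector) and `degenerate` (flagged constant categories).
#' @export
cluster_genes <- function(matrix, k = NULL) {
  vaf <- if (inherits(matrix, "mutation_matrix")) matrix$max_vaf else as.matrix(matrix)
  vaf <- vaf[, order(colnames(vaf)), drop = FALSE]
  p <- ncol(vaf)
  if (p < 2) stop("need at least 2 categories to cluster", call. = FALSE)
  constant <- apply(vaf, 2, function(x) length(unique(x)) < 2)
  d <- matrix(1, p, p, dimnames = list(colnames(vaf), colnames(vaf)))
  diag(d) <- 0
  ok <- which(!constant)
  if (length(ok) >= 2) {
    rho <- suppressWarnings(stats::cor(vaf[, ok, drop = FALSE],
                                       method = "spearman"))
    d[ok, ok] <- 1 - abs(rho)
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  if (is.null(k)) {
    clusters <- stats::cutree(hc, h = max(hc$height) / 2)
  } else {
    clusters <- stats::cutree(hc, k = k)
  }
  list(hclust = hc, distance = stats::as.dist(d), clusters = clusters,
       degenerate = colnames(vaf)[constant])
}
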