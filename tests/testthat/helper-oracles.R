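# Independent brute-force oracles used to validate the package's
# implementations on small fixtures. These deliberately share no code with
# the implementation paths they check.

# Two-sided exact p-value for a 2x2 table by full enumeration of all tables
# with the observed margins (hypergeometric probabilities; two-sided by
# summing tables with probability <= observed, with a small tolerance for
# floating-point equality, as in the classical definition).
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Step-up Benjamini-Hochberg by direct evaluation of the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  ps <- p[o]
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(ps[i:m] * m / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Breslow-ties Cox log partial likelihood with left truncation, evaluated
# directly from the definition; used with a grid/golden-section maximiser.
oracle_log_pl <- function(beta, entry, exit, status, x) {
  x <- as.matrix(x)
  eta <- as.numeric(x %*% beta)
  ll <- 0
  for (i in which(status == 1)) {
    risk <- entry < exit[i] & exit >= exit[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

oracle_cox_beta <- function(entry, exit, status, x, lower = -8, upper = 8) {
  stats::optimize(function(b) oracle_log_pl(b, entry, exit, status, x),
                  c(lower, upper), maximum = TRUE, tol = 1e-9)$maximum
}

# Kaplan-Meier by hand: product over distinct event times of (1 - d/n),
# events processed before censorings at tied times.
oracle_km <- function(times, status) {
  ts <- sort(unique(times[status == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (k in seq_along(ts)) {
    n_risk <- sum(times >= ts[k])
    d <- sum(times == ts[k] & status == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  data.frame(time = ts, surv = surv)
}

# Censoring KM evaluator (events before censorings at ties), returning
# G(t) and the left limit G(t-).
oracle_censor_km <- function(times, status) {
  cens <- oracle_km(times, 1 - status)
  G <- function(t) {
    vapply(t, function(u) {
      v <- cens$surv[cens$time <= u]
      if (length(v)) v[length(v)] else 1
    }, numeric(1))
  }
  G_minus <- function(t) {
    vapply(t, function(u) {
      v <- cens$surv[cens$time < u]
      if (length(v)) v[length(v)] else 1
    }, numeric(1))
  }
  list(G = G, G_minus = G_minus)
}

# Harrell's C by exhaustive enumeration of ordered pairs.
oracle_harrell_c <- function(times, status, risk) {
  num <- 0; den <- 0
  n <- length(times)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (status[i] == 1 && times[i] < times[j]) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

# IPCW Brier by direct per-subject weight computation.
oracle_ipcw_brier <- function(times, status, pred, horizon) {
  cw <- oracle_censor_km(times, status)
  total <- 0
  n <- length(times)
  for (i in seq_len(n)) {
    if (times[i] <= horizon && status[i] == 1) {
      total <- total + (1 - pred[i])^2 / cw$G_minus(times[i])
    } else if (times[i] > horizon) {
      total <- total + (0 - pred[i])^2 / cw$G(horizon)
    }
  }
  total / n
}

# IPCW cumulative/dynamic AUC by exhaustive weighted pair enumeration.
oracle_ipcw_auc <- function(times, status, risk, horizon) {
  cw <- oracle_censor_km(times, status)
  cases <- which(times <= horizon & status == 1)
  controls <- which(times > horizon)
  num <- 0; den <- 0
  for (i in cases) for (j in controls) {
    w <- (1 / cw$G_minus(times[i])) * (1 / cw$G(horizon))
    den <- den + w
    if (risk[i] > risk[j]) num <- num + w
    else if (risk[i] == risk[j]) num <- num + w / 2
  }
  num / den
}

# --- exhaustive DAG search over <=3 labelled nodes ------------------------

# Independent family BIC for a Bernoulli node (same statistical definition,
# written from the formula rather than shared code).
oracle_family_bic <- function(x, parents, n) {
  if (NCOL(parents) == 0 || is.null(parents)) {
    cfgs <- list(rep(TRUE, length(x)))
  } else {
    pm <- as.matrix(parents)
    keys <- apply(pm, 1, paste, collapse = ",")
    cfgs <- lapply(unique(keys), function(k) keys == k)
    # absent configurations contribute 0 likelihood but still count as
    # parameters in 2^k
  }
  ll <- 0
  for (sel in cfgs) {
    m <- sum(sel); m1 <- sum(x[sel])
    if (m == 0) next
    p <- m1 / m
    if (p > 0) ll <- ll + m1 * log(p)
    if (p < 1) ll <- ll + (m - m1) * log(1 - p)
  }
  k <- if (is.null(parents)) 0 else NCOL(as.matrix(parents))
  ll - 0.5 * log(n) * 2^k
}

oracle_bic_score <- function(data, adj) {
  n <- nrow(data)
  sum(vapply(seq_len(ncol(data)), function(j) {
    pa <- which(adj[, j] == 1)
    oracle_family_bic(data[, j],
                      if (length(pa)) data[, pa, drop = FALSE] else NULL, n)
  }, numeric(1)))
}

oracle_all_dags <- function(p) {
  stopifnot(p <= 3)
  pairs <- utils::combn(p, 2)
  n_pair <- ncol(pairs)
  dags <- list()
  # each unordered pair is absent, forward, or backward
  for (code in seq_len(3^n_pair) - 1) {
    adj <- matrix(0L, p, p)
    c0 <- code
    for (k in seq_len(n_pair)) {
      st <- c0 %% 3; c0 <- c0 %/% 3
      if (st == 1) adj[pairs[1, k], pairs[2, k]] <- 1L
      if (st == 2) adj[pairs[2, k], pairs[1, k]] <- 1L
    }
    # acyclic iff the transitive closure has an empty diagonal
    closure <- adj + adj %*% adj + adj %*% adj %*% adj
    if (sum(diag(closure)) == 0) dags[[length(dags) + 1L]] <- adj
  }
  dags
}

oracle_best_dag_score <- function(data) {
  dags <- oracle_all_dags(ncol(data))
  max(vapply(dags, function(a) oracle_bic_score(data, a), numeric(1)))
}

# Simple single-transition survival fixture builder (msdata layout).
make_msdata <- function(exit, status, x, transition = "1->3",
                        entry = rep(0, length(exit))) {
  data.frame(patient_id = sprintf("S%02d", seq_along(exit)),
             transition = transition, entry = entry, exit = exit,
             status = status, x = x, stringsAsFactors = FALSE)
}

# Small variant-row builder.
make_variant <- function(patient_id, gene, effect = "missense", vaf = 30,
                         pathogenicity = "pathogenic", pop_maf = 0,
                         is_driver = 0L) {
  n <- max(length(patient_id), length(gene))
  data.frame(patient_id = rep_len(patient_id, n), gene = rep_len(gene, n),
             effect = rep_len(effect, n), vaf = rep_len(vaf, n),
             pathogenicity = rep_len(pathogenicity, n),
             pop_maf = rep_len(pop_maf, n),
             is_driver = rep_len(is_driver, n), stringsAsFactors = FALSE)
}

empty_cnv <- function() {
  data.frame(patient_id = character(0), region = character(0),
             kind = character(0), stringsAsFactors = FALSE)
}
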