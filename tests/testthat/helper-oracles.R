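# Independent oracles and small data builders shared across the test files.
# These deliberately re-derive quantities by brute force (double loops,
# direct enumeration, 1-D grid optimization) so they stay independent of the
# package's implementation paths.

# Brute-force best split: direct evaluation of every midpoint between
# consecutive sorted unique values, straight from the Gini definition.
oracle_best_split <- function(x, y, weights = NULL, min_leaf = 1) {
  if (is.null(weights)) weights <- rep(1, length(x))
  ux <- sort(unique(x))
  if (length(ux) < 2L) return(NULL)
  gini <- function(idx) {
    w <- weights[idx]
    if (sum(w) == 0) return(0)
    p <- sum(w[y[idx]]) / sum(w)
    1 - p^2 - (1 - p)^2
  }
  all_idx <- seq_along(x)
  W <- sum(weights)
  g_parent <- gini(all_idx)
  best <- NULL
  for (i in seq_len(length(ux) - 1L)) {
    thr <- (ux[i] + ux[i + 1L]) / 2
    left <- x <= thr
    if (sum(left) < min_leaf || sum(!left) < min_leaf) next
    dec <- g_parent -
      sum(weights[left]) / W * gini(which(left)) -
      sum(weights[!left]) / W * gini(which(!left))
    if (is.null(best) || dec > best$impurity_decrease + 1e-12) {
      best <- list(threshold = thr, impurity_decrease = dec)
    }
  }
  best
}

# Pairwise-comparison AUROC: fraction of positive-negative pairs where the
# positive scores higher, ties counting one half.
oracle_pairwise_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Cox partial log-likelihood for a single covariate with no tied event
# times, straight from the definition (risk set = subjects still under
# observation at the event time).
oracle_cox_loglik <- function(time, event, x) {
  function(beta) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
  }
}

# Two-group labelled feature sample used for threshold-learner recovery:
# deficient carriers have lower RDW and a higher (less negative) glucose gap.
make_learner_sample <- function(n, seed, prevalence = 0.12) {
  set.seed(seed)
  pos <- stats::runif(n) < prevalence
  tibble::tibble(
    rdw = ifelse(pos, stats::rnorm(n, 11.2, 0.8), stats::rnorm(n, 14.0, 1.2)),
    gg = ifelse(pos, stats::rnorm(n, -8, 10), stats::rnorm(n, -27, 12)),
    label = pos
  )
}

# Minimal draw table builder.
make_draws <- function(glucose, participant_id = "P1",
                       draw_date = as.Date("2015-01-01") + seq_along(glucose),
                       hba1c = 5.6, rdw = 13.5) {
  tibble::tibble(
    participant_id = participant_id,
    draw_date = draw_date,
    glucose = glucose,
    hba1c = hba1c,
    rdw = rdw
  )
}

# Two-group exponential survival sample with a planted hazard ratio.
make_survival_sample <- function(n, hr, seed, base_rate = 0.05,
                                 exposed_fraction = 0.3) {
  set.seed(seed)
  grp <- stats::rbinom(n, 1, exposed_fraction)
  t_event <- stats::rexp(n, base_rate * hr^grp)
  t_censor <- stats::runif(n, 2, 30)
  tibble::tibble(
    time_years = pmin(t_event, t_censor),
    event = t_event <= t_censor,
    grp = grp
  )
}
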