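# Independent brute-force oracles used to check the implementation paths.
# These deliberately avoid ranks, survfit/survdiff, and the package's own
# ROC machinery: AUC by explicit pair counting, exact rank-sum p by full
# enumeration with per-assignment pair counting, Kaplan-Meier by a literal
# product-limit loop, and the two-group log-rank by explicit O/E/V
# tabulation over pooled event times.

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

oracle_exact_p <- function(scores, labels) {
  n <- length(scores)
  n1 <- sum(labels == 1)
  u_of <- function(idx) {
    pos <- scores[idx]
    neg <- scores[setdiff(seq_len(n), idx)]
    u <- 0
    for (p in pos) for (q in neg) u <- u + (p > q) + 0.5 * (p == q)
    u
  }
  mu <- n1 * (n - n1) / 2
  u_obs <- u_of(which(labels == 1))
  us <- apply(utils::combn(n, n1), 2L, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

oracle_km <- function(times, events) {
  et <- sort(unique(times[events == 1]))
  s <- 1
  surv <- n_at <- d_at <- numeric(0)
  for (t in et) {
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
    surv <- c(surv, s)
    n_at <- c(n_at, n_risk)
    d_at <- c(d_at, d)
  }
  list(event_times = et, n_at_risk = n_at, n_events = d_at, survival = surv)
}

oracle_logrank2 <- function(t1, e1, t2, e2) {
  et <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  O <- E <- V <- 0
  for (t in et) {
    n1 <- sum(t1 >= t)
    n2 <- sum(t2 >= t)
    nn <- n1 + n2
    d <- sum(t1 == t & e1 == 1) + sum(t2 == t & e2 == 1)
    O <- O + sum(t1 == t & e1 == 1)
    E <- E + d * n1 / nn
    if (nn > 1) V <- V + d * (n1 / nn) * (1 - n1 / nn) * (nn - d) / (nn - 1)
  }
  (O - E)^2 / V
}

oracle_youden_scan <- function(scores, labels) {
  s <- sort(unique(scores))
  mids <- (s[-length(s)] + s[-1]) / 2
  best <- -Inf
  best_cut <- NA_real_
  for (cm in mids) {
    j <- mean(scores[labels == 1] >= cm) - mean(scores[labels == 0] >= cm)
    if (j > best + 1e-12) {  # strict improvement: lowest cutoff kept on ties
      best <- j
      best_cut <- cm
    }
  }
  best_cut
}

# Random censored cohort with heavy ties (months-resolution follow-up).
rand_surv_cohort <- function(n) {
  times <- sample(1:15, n, replace = TRUE)
  events <- stats::rbinom(n, 1, 0.6)
  events[1] <- 1  # guarantee at least one event
  list(times = times, events = events)
}

# Random binary-labelled score set with both classes present.
rand_binary <- function(n, tied = FALSE) {
  scores <- if (tied) sample(1:5, n, replace = TRUE) else stats::rnorm(n)
  n1 <- sample(seq_len(n - 1L), 1L)
  labels <- sample(c(rep(1, n1), rep(0, n - n1)))
  list(scores = scores, labels = labels)
}

# Handcrafted six-sample cohort covering all six subgroup labels exactly once.
six_label_fixture <- function() {
  expr <- rbind(
    `216836_s_at` = c(4000, 2500, 1000, 4000, 2500, 1000),
    `205225_at`   = c(900, 900, 900, 100, 100, 100))
  colnames(expr) <- paste0("P", 1:6)
  clinical <- data.frame(
    sample_id = paste0("P", 1:6),
    ihc_score = c(3, 1, 0, 3, 2, 0),
    faint_staining_flag = c(NA, NA, TRUE, NA, NA, TRUE),
    fish_ratio = c(4, 1.2, 1.1, 5, 1.5, 1.0),
    fish_status = c("positive", "negative", "negative",
                    "positive", "negative", "negative"),
    hr_status = NA_character_,
    time_rfs = c(10, 20, 30, 40, 50, 60),
    event_rfs = c(1, 0, 1, 0, 1, 0),
    time_dmfs = NA_real_, event_dmfs = NA_real_,
    time_os = NA_real_, event_os = NA_real_,
    stringsAsFactors = FALSE)
  list(expression = expr, clinical = clinical)
}
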