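# shared fixtures and independent oracles

tiny_cfg <- function(...) effect_config(n_subjects = 2, n_sessions = 3, ...)

fixture_state <- function(pleasant = 0, arousal = 0, engagement = 3,
                          difficulty = 0) {
  list(pleasant = pleasant, arousal = arousal, engagement = engagement,
       subjective_difficulty = difficulty, flow = 0.5, subject_skill = 1,
       period = 1L)
}

# a session object with motion streams only, short duration
fixture_motion_session <- function(state = fixture_state(), duration = 35,
                                   seed = 1) {
  sess <- list(
    subject = 1, session = 1, period = 1, complexity = "simple",
    working_time_s = duration, human_errors = 0,
    order_sheet = synthesize_order_sheets("simple", seed = seed),
    questionnaire = state[c("pleasant", "arousal", "engagement")],
    streams = synthesize_motion(state, duration, effect_config(), seed = seed)
  )
  sess$questionnaire$difficulty <- 0
  class(sess) <- "picking_session"
  sess
}

# hand-rolled order sheet for task-complexity oracles
manual_sheet <- function(area_lists, complexity_class = "simple") {
  structure(list(
    complexity_class = complexity_class,
    lists = lapply(area_lists, function(a) {
      data.frame(area = a, item = rep(1L, length(a)), count = rep(1L, length(a)),
                 stringsAsFactors = FALSE)
    })
  ), class = "order_sheet")
}

## ---- independent oracles ---------------------------------------------------

# brute-force peak-valley enumeration: walk the series, classify extrema by
# direct neighbour comparison, normalize, band-filter, summarize raw values
oracle_peak_valley <- function(x, th) {
  ext <- c()
  for (i in 2:(length(x) - 1)) {
    if ((x[i] > x[i - 1] && x[i] > x[i + 1]) ||
        (x[i] < x[i - 1] && x[i] < x[i + 1])) {
      ext <- c(ext, x[i])
    }
  }
  lo <- min(x); hi <- max(x)
  if (hi == lo || is.null(ext)) {
    return(list(count = 0L, mean = NA_real_, min = NA_real_, max = NA_real_))
  }
  nrm <- (ext - lo) / (hi - lo)
  adopted <- ext[nrm <= 0.5 - th / 2 | nrm >= 0.5 + th / 2]
  if (!length(adopted)) {
    return(list(count = 0L, mean = NA_real_, min = NA_real_, max = NA_real_))
  }
  list(count = length(adopted), mean = mean(adopted),
       min = min(adopted), max = max(adopted))
}

# the Brunner-Munzel statistic alone (for the permutation oracle)
oracle_bm_stat <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  R <- rank(c(x, y)); R1 <- R[1:n1]; R2 <- R[(n1 + 1):N]
  r1 <- rank(x); r2 <- rank(y)
  m1 <- mean(R1); m2 <- mean(R2)
  v1 <- sum((R1 - r1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((R2 - r2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  pooled <- n1 * v1 + n2 * v2
  if (pooled <= 0) return(sign(m2 - m1) * Inf)
  (n1 * n2 * (m2 - m1)) / (N * sqrt(pooled))
}

# exhaustive permutation p-value of the BM statistic (two-sided)
oracle_bm_permutation_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  obs <- abs(oracle_bm_stat(x, y))
  stats_perm <- apply(idx, 2, function(ii) {
    abs(oracle_bm_stat(pooled[ii], pooled[-ii]))
  })
  mean(stats_perm >= obs - 1e-12)
}

# logistic map series (fully chaotic regime r = 4); Lyapunov exponent ln 2
logistic_map <- function(n, x0 = 0.2, burn = 100) {
  x <- x0
  for (i in seq_len(burn)) x <- 4 * x * (1 - x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- 4 * x * (1 - x)
    out[i] <- x
  }
  out
}

# synthetic feature matrix with planted linear structure, for CV tests
synthetic_features <- function(n_subjects, n_sessions, noise = 0.3,
                               subject_offset = 0, seed = 1) {
  set.seed(seed)
  n <- n_subjects * n_sessions
  subject <- rep(seq_len(n_subjects), each = n_sessions)
  pleasant <- sample(-3:3, n, replace = TRUE)
  arousal <- sample(-3:3, n, replace = TRUE)
  engagement <- sample(1:5, n, replace = TRUE)
  offs <- rnorm(n_subjects, 0, subject_offset)[subject]
  X <- cbind(
    f1 = pleasant + rnorm(n, 0, noise) + offs,
    f2 = arousal + rnorm(n, 0, noise) + offs,
    f3 = engagement + rnorm(n, 0, noise) + offs,
    f4 = rnorm(n), f5 = rnorm(n), f6 = rnorm(n), f7 = rnorm(n),
    f8 = rnorm(n), f9 = rnorm(n), f10 = rnorm(n), f11 = rnorm(n),
    f12 = rnorm(n)
  )
  meta <- data.frame(subject = subject,
                     session = rep(seq_len(n_sessions), n_subjects),
                     pleasant = pleasant, arousal = arousal,
                     engagement = engagement, difficulty = 0,
                     working_time_s = 45)
  structure(list(X = X, meta = meta, device_group = "motion"),
            class = "feature_matrix")
}

# fast network spec for unit tests (lighter regularization than the study
# architecture so small toy problems actually converge)
tiny_spec <- function(seed = 1, ...) {
  network_spec(units = 24L, epochs = 60L, pretrain_epochs = 8L,
               patience = 12L, dropout = 0.3, seed = seed, ...)
}
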