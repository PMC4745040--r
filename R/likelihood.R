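#' Create a parameter set
#'
#' Per-species rates of the assembly process and the diversity limit.  All
#' rates are events per lineage per million years.
#'
#' @param gamma immigration rate from the mainland.
#' @param lambda_c in-situ cladogenesis rate.
#' @param lambda_a anagenesis rate (conversion of a non-endemic island
#'   population into an endemic species).
#' @param mu island extinction rate.
#' @param K_prime carrying capacity: cladogenesis and immigration rates
#'   decline linearly with the diversity of the colonising lineage and vanish
#'   at `K_prime`; `Inf` (the default) disables the feedback.
#' @return an object of class `parameter_set`.
#' @export
#' @examples
#' parameter_set(gamma = 0.01, lambda_c = 0.5, lambda_a = 1, mu = 0.2,
#'               K_prime = 15)
parameter_set <- function(gamma, lambda_c, lambda_a, mu, K_prime = Inf) {
  p <- structure(list(gamma = as.numeric(gamma),
                      lambda_c = as.numeric(lambda_c),
                      lambda_a = as.numeric(lambda_a),
                      mu = as.numeric(mu),
                      K_prime = as.numeric(K_prime)),
                 class = "parameter_set")
  rates <- unlist(p[c("gamma", "lambda_c", "lambda_a", "mu")])
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and >= 0", call. = FALSE)
  if (is.na(p$K_prime) || p$K_prime <= 0)
    stop("K_prime must be positive (possibly Inf)", call. = FALSE)
  p
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf(
    "rates/My: gamma %.4g, lambda_c %.4g, lambda_a %.4g, mu %.4g; K' %s\n",
    x$gamma, x$lambda_c, x$lambda_a, x$mu,
    if (is.finite(x$K_prime)) format(x$K_prime, digits = 4) else "Inf"))
  invisible(x)
}

#' Diversity-dependent per-species rate
#'
#' Linear decline of a base rate with the number of species `n` already in
#' the colonising lineage, clamped at zero at the carrying capacity:
#' `max(0, base * (1 - n / K_prime))`.  With `K_prime = Inf` the base rate is
#' returned unchanged.
#'
#' @param base_rate non-negative per-species rate.
#' @param n current species count of the lineage (vectorised).
#' @param K_prime carrying capacity.
#' @return the effective rate(s).
#' @export
#' @examples
#' dd_rate(0.5, 0:6, K_prime = 5)
dd_rate <- function(base_rate, n, K_prime) {
  stopifnot(base_rate >= 0, all(n >= 0))
  if (!is.finite(K_prime)) return(rep(base_rate, length(n)))
  pmax(0, base_rate * (1 - n / K_prime))
}

# ---------------------------------------------------------------------------
# Hidden-state vectors
#
# The likelihood machinery tracks, per colonist, probability vectors over the
# hidden number n of island species that are not in the phylogeny,
# truncated at n_max:
#   k = 0 or k >= 2:  [ Q_n^k ; Q_n^{M,k} ]           (mainland pop absent /
#                                                       present on island)
#   k = 1:            [ Q_n^1 ; Q_n^{M,1} ; Q_{M,n} ]  (third channel: the
#                      colonist that will survive to the present and has not
#                      yet diverged or speciated)
# Vectors may be rescaled to avoid underflow; the accumulated log scale is
# carried in `logscale`.
# ---------------------------------------------------------------------------

#' Create a hidden-state probability vector
#'
#' @param k number of phylogeny lineages represented (0, 1, 2, ...).
#' @param n_max truncation bound for the hidden species count.
#' @param t current forward time (My since island birth).
#' @param q optional numeric state vector (length `2*(n_max+1)`, or
#'   `3*(n_max+1)` when `k == 1`); the default is the process start:
#'   probability 1 of an empty island with the mainland species absent.
#' @param logscale accumulated log scale factor.
#' @return an object of class `q_state`.
#' @export
q_state <- function(k = 0L, n_max = 10L, t = 0, q = NULL, logscale = 0) {
  k <- as.integer(k); n_max <- as.integer(n_max)
  if (n_max < 1) stop("n_max must be >= 1", call. = FALSE)
  nchan <- if (k == 1L) 3L else 2L
  lx <- n_max + 1L
  if (is.null(q)) {
    if (k != 0L) stop("a default state is only defined for k = 0",
                      call. = FALSE)
    q <- c(1, rep(0, 2L * lx - 1L))
  }
  if (length(q) != nchan * lx)
    stop("state vector has length ", length(q), ", expected ", nchan * lx,
         call. = FALSE)
  if (any(q < -1e-8))
    stop("state vector has substantially negative entries", call. = FALSE)
  structure(list(k = k, n_max = n_max, t = as.numeric(t),
                 q = pmax(q, 0), logscale = as.numeric(logscale)),
            class = "q_state")
}

#' Extract one channel of a hidden-state vector
#'
#' Channels: `"plain"` (mainland species absent from the island),
#' `"mainland"` (mainland species present), and, while `k = 1`,
#' `"colonist"` (the not-yet-diverged population whose lineage survives to
#' the present).  Entries run over the hidden species count n = 0..n_max.
#'
#' @param state a [q_state()].
#' @param channel channel name.
#' @return numeric vector of length `n_max + 1`.
#' @export
q_channel <- function(state, channel = c("plain", "mainland", "colonist")) {
  channel <- match.arg(channel)
  lx <- state$n_max + 1L
  idx <- switch(channel, plain = 1:lx, mainland = lx + 1:lx,
                colonist = 2L * lx + 1:lx)
  if (channel == "colonist" && state$k != 1L)
    stop("the colonist-surviving channel exists only while k = 1",
         call. = FALSE)
  state$q[idx]
}

# relative probability mass sitting in the top two hidden-n cells; used to
# decide whether the truncation bound must be raised
tail_mass <- function(state) {
  lx <- state$n_max + 1L
  nchan <- length(state$q) / lx
  tot <- sum(state$q)
  if (tot <= 0) return(0)
  idx <- as.vector(outer(c(lx - 1L, lx), (seq_len(nchan) - 1L) * lx, `+`))
  sum(state$q[idx]) / tot
}

#' Advance the hidden-state vector between observed events
#'
#' Integrates the master equations over `[t_from, t_to]`.  The generator is
#' constant over a segment, so the propagation uses a matrix exponential and
#' is exact up to the truncation at `n_max`: integrating a segment in one
#' step or in several gives identical results.
#'
#' @param state a [q_state()].
#' @param params a [parameter_set()].
#' @param t_to target forward time (> `state$t`).
#' @param t_from start time; defaults to the state's own clock.
#' @return the advanced [q_state()], with attribute `"tail_mass"` giving the
#'   relative probability mass in the top truncation cells.
#' @export
integrate_master <- function(state, params, t_to, t_from = state$t) {
  stopifnot(inherits(state, "q_state"), inherits(params, "parameter_set"))
  if (t_from != state$t)
    stop("t_from does not match the state clock", call. = FALSE)
  if (t_to < t_from) stop("t_to must be >= t_from", call. = FALSE)
  if (t_to == t_from) return(state)
  q <- .cpp_propagate(state$q, t_to - t_from, state$k, state$n_max,
                      params$gamma, params$lambda_c, params$lambda_a,
                      params$mu, params$K_prime)
  q <- as.numeric(q)
  if (any(!is.finite(q)))
    stop("master-equation propagation produced non-finite probabilities ",
         "(k = ", state$k, ", dt = ", t_to - t_from, ")", call. = FALSE)
  # clamp matrix-exponential roundoff
  q[q < 0] <- 0
  out <- state
  out$q <- q
  out$t <- t_to
  s <- sum(q)
  if (s > 0 && s < 1e-40) {   # rescale long products away from underflow
    out$q <- q / s
    out$logscale <- out$logscale + log(s)
  }
  attr(out, "tail_mass") <- tail_mass(out)
  out
}

#' Apply the observed colonisation event
#'
#' Switches the state from the pre-colonisation regime (k = 0) to the
#' single-lineage regime (k = 1).  The colonising species arrives at the
#' diversity-dependent immigration rate, founding (or replacing) the island
#' population whose lineage is observed to survive to the present:
#' `Q_{M,n}(t_c) = gamma_n Q_n^0 + gamma_{n+1} Q_n^{M,0}`.  The second term
#' covers arrival onto a still-conspecific resident population, which the
#' later immigrant replaces, resetting the divergence time; it is required
#' for the likelihood to reduce to the most-recent-arrival density of a
#' Poisson process in the immigration-only limit.  The result is a density
#' with respect to the colonisation time, not a probability.
#'
#' @param state a [q_state()] with `k = 0`.
#' @param params a [parameter_set()].
#' @return a [q_state()] with `k = 1`.
#' @export
apply_colonisation <- function(state, params) {
  stopifnot(inherits(state, "q_state"))
  if (state$k != 0L)
    stop("colonisation can only be applied in the k = 0 regime", call. = FALSE)
  n <- 0:state$n_max
  qM <- dd_rate(params$gamma, n, params$K_prime) * q_channel(state, "plain") +
    dd_rate(params$gamma, n + 1, params$K_prime) *
      q_channel(state, "mainland")
  lx <- state$n_max + 1L
  q_state(k = 1L, n_max = state$n_max, t = state$t,
          q = c(rep(0, 2L * lx), qM), logscale = state$logscale)
}

#' Apply an observed branching (speciation) event
#'
#' Updates the state at a node of the island clade, incrementing k.  At the
#' first branching (k: 1 -> 2) the not-yet-diverged colonist channel is
#' folded in and emptied:
#' `Q_n^2 = lambda^c_{n+1} (Q_n^1 + Q_{M,n})`,
#' `Q_n^{M,2} = lambda^c_{n+2} Q_n^{M,1}`.
#' At later branchings (k -> k+1, k >= 2):
#' `Q_n^{k+1} = lambda^c_{n+k} Q_n^k`,
#' `Q_n^{M,k+1} = lambda^c_{n+k+1} Q_n^{M,k}`.
#'
#' @param state a [q_state()] with `k >= 1`.
#' @param params a [parameter_set()].
#' @return a [q_state()] with `k` incremented.
#' @export
apply_branching <- function(state, params) {
  stopifnot(inherits(state, "q_state"))
  if (state$k < 1L)
    stop("branching applied before colonisation (k = 0)", call. = FALSE)
  n <- 0:state$n_max
  k <- state$k
  if (k == 1L) {
    qk <- dd_rate(params$lambda_c, n + 1, params$K_prime) *
      (q_channel(state, "plain") + q_channel(state, "colonist"))
    qMk <- dd_rate(params$lambda_c, n + 2, params$K_prime) *
      q_channel(state, "mainland")
  } else {
    qk <- dd_rate(params$lambda_c, n + k, params$K_prime) *
      q_channel(state, "plain")
    qMk <- dd_rate(params$lambda_c, n + k + 1, params$K_prime) *
      q_channel(state, "mainland")
  }
  q_state(k = k + 1L, n_max = state$n_max, t = state$t, q = c(qk, qMk),
          logscale = state$logscale)
}

# default truncation bound for a record (a numerical choice the model does
# not fix: generous for finite K', at least twice the observed clade size)
default_n_max <- function(record, params = NULL) {
  csize <- record_n_species(record)
  nm <- max(10, 2 * csize, record$n_missing + 5)
  # a finite K' bounds the hidden dimension at ~K'; for very large K' the
  # feedback is negligible at reachable n, so the bound is capped (the
  # doubling escalation still verifies the choice)
  if (!is.null(params) && is.finite(params$K_prime))
    nm <- max(nm, min(ceiling(params$K_prime) + 5, 200))
  as.integer(nm)
}

# forward-time event vector consumed by the compiled record chain
record_event_times <- function(record, island_age) {
  tp <- island_age
  switch(record$status,
         numeric(),                                          # 1
         tp - min(record$colonisation_time, tp, na.rm = TRUE), # 2: bound
         tp - record$colonisation_time,                      # 3
         c(tp - record$colonisation_time,
           sort(tp - record$branching_times)),               # 4
         c(tp - record$colonisation_time,
           sort(tp - record$branching_times)))               # 5
}

# single pass of the per-record likelihood at a fixed truncation bound.
# engine "cpp": sparse uniformisation (fast path used for fitting);
# engine "r": the exported q_state operations backed by a dense matrix
# exponential -- an independent numerical route used for cross-checking.
loglik_record_once <- function(record, params, island_age, n_max,
                               engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (engine == "cpp") {
    res <- .cpp_loglik_record(record$status,
                              record_event_times(record, island_age),
                              island_age, record$n_missing, n_max,
                              params$gamma, params$lambda_c,
                              params$lambda_a, params$mu, params$K_prime)
    if (is.na(res$ll))
      stop("non-finite likelihood for record '", record$label, "' (",
           paste(sprintf("%s=%g", c("gamma", "lambda_c", "lambda_a", "mu",
                                    "K'"), unlist(params)), collapse = ", "),
           ")", call. = FALSE)
    return(res$ll)
  }
  tp <- island_age
  read_out <- function(state, channel) {
    v <- q_channel(state, channel)[record$n_missing + 1L]
    if (v <= 0) return(-Inf)
    log(v) + state$logscale
  }
  if (record$status == 1L) {
    st <- integrate_master(q_state(0L, n_max), params, tp)
    return(read_out(st, "plain"))
  }
  if (record$status == 2L) {
    bound <- min(record$colonisation_time, island_age, na.rm = TRUE)
    st <- q_state(0L, n_max, t = tp - bound)
    st <- integrate_master(st, params, tp)
    return(read_out(st, "mainland"))
  }
  tc <- tp - record$colonisation_time
  st <- integrate_master(q_state(0L, n_max), params, tc)
  st <- apply_colonisation(st, params)
  if (record$status == 3L) {
    st <- integrate_master(st, params, tp)
    return(read_out(st, "colonist"))
  }
  for (b in record$branching_times) {   # ages, oldest first
    st <- integrate_master(st, params, tp - b)
    st <- apply_branching(st, params)
  }
  st <- integrate_master(st, params, tp)
  read_out(st, if (record$status == 5L) "mainland" else "plain")
}

#' Log-likelihood of one colonist record
#'
#' Computes the log probability (a log density where observed event times are
#' conditioned on) of a single data entry under the model, by threading the
#' hidden-state vector through the observed colonisation and branching times
#' and reading off the channel that matches the record's status at the
#' present:
#' * status 1: probability of no extant descendants (`Q_0^0(t_p)`),
#'   integrating over all unobserved histories;
#' * status 2: probability that a non-endemic population is present, with
#'   colonisation allowed anywhere after the record's upper bound
#'   (`Q_n^{M,0}(t_p)` started from the bound);
#' * status 3: density of the observed divergence time of a non-endemic
#'   population (`Q_{M,n}(t_p)`): no re-immigration afterwards, which would
#'   have reset it;
#' * status 4: density of the endemic clade's colonisation and branching
#'   times with the mainland species absent (`Q_n^k(t_p)`);
#' * status 5: as 4, with the mainland species present (`Q_n^{M,k}(t_p)`).
#'
#' The hidden-species truncation starts at
#' `max(10, K'+5, 2 x clade size)` and doubles until the log-likelihood
#' moves by less than `1e-6`, up to a hard cap.
#'
#' @param record a [colonist_record()].
#' @param params a [parameter_set()].
#' @param island_age island age (My).
#' @param n_max optional fixed truncation bound (disables escalation).
#' @param n_max_cap hard cap for the escalation (default 1024).
#' @param engine `"cpp"` (sparse uniformisation, default) or `"r"` (the
#'   exported [q_state()] operations backed by a dense matrix exponential);
#'   the two are independent numerical routes to the same equations.
#' @return the log-likelihood (scalar).
#' @export
loglik_colonist <- function(record, params, island_age, n_max = NULL,
                            n_max_cap = 1024L, engine = "cpp") {
  validate_colonist_record(record)
  if (!is.null(n_max))
    return(loglik_record_once(record, params, island_age, n_max, engine))
  nm <- default_n_max(record, params)
  ll <- loglik_record_once(record, params, island_age, nm, engine)
  repeat {
    if (nm >= n_max_cap)
      stop("hidden-species truncation cap (", n_max_cap, ") reached for ",
           "record '", record$label, "'", call. = FALSE)
    nm2 <- min(2L * nm, n_max_cap)
    ll2 <- loglik_record_once(record, params, island_age, nm2, engine)
    conv <- (is.infinite(ll) && is.infinite(ll2)) || abs(ll2 - ll) < 1e-6
    if (conv) return(ll2)
    nm <- nm2
    ll <- ll2
  }
}

#' Log-likelihood of a full island dataset
#'
#' Mainland species are independent, so the community log-likelihood is the
#' sum of the per-colonist log densities plus, for every lineage class, the
#' log probability of leaving no extant descendants for each of the
#' mainland-pool species of that class that is not among the observed
#' colonists.
#'
#' @param dataset an [island_dataset()].
#' @param params_by_class named list of [parameter_set()] objects covering
#'   every lineage class of the dataset.  A single unnamed `parameter_set`
#'   is recycled for all classes.
#' @param condition if `TRUE`, condition on the island being non-empty at
#'   the present (off by default; the likelihood is then divided by
#'   one minus the probability that no mainland species has extant island
#'   descendants).
#' @param n_max `NULL` (per-record bound with doubling escalation), a fixed
#'   integer bound, or `"auto"` (per-record default bound without
#'   escalation; the fitting search path, verified afterwards).
#' @param n_max_mult multiplier applied to `"auto"` bounds (used to verify
#'   truncation at the optimum).
#' @param engine numerical engine, as in [loglik_colonist()].
#' @param .validate skip input validation (internal hot path).
#' @return the log-likelihood (scalar; `-Inf` for impossible data).
#' @export
#' @examples
#' d <- island_dataset(4, 1000,
#'   list(colonist_record("a", 3, 1.0)), c(all = 1))
#' p <- parameter_set(0.01, 0.3, 1, 0.1)
#' loglik_dataset(d, list(all = p))
loglik_dataset <- function(dataset, params_by_class, condition = FALSE,
                           n_max = NULL, n_max_mult = 1L, engine = "cpp",
                           .validate = TRUE) {
  if (.validate) validate_island_dataset(dataset)
  if (inherits(params_by_class, "parameter_set"))
    params_by_class <- setNames(
      rep(list(params_by_class), length(dataset$class_fractions)),
      names(dataset$class_fractions))
  classes <- names(dataset$class_fractions)
  miss <- setdiff(classes, names(params_by_class))
  if (length(miss))
    stop("no parameter set supplied for class(es): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ll <- 0
  obs <- vapply(dataset$colonists, function(r) r$lineage_class, character(1))
  auto <- identical(n_max, "auto")
  for (rec in dataset$colonists) {
    p <- params_by_class[[rec$lineage_class]]
    nm <- if (auto) n_max_mult * default_n_max(rec, p) else n_max
    ll <- ll + if (auto || !.validate)
      loglik_record_once(rec, p, dataset$island_age, nm, engine)
    else loglik_colonist(rec, p, dataset$island_age, n_max = nm,
                         engine = engine)
  }
  empty_rec <- colonist_record("<unobserved>", 1L)
  for (cl in classes) {
    pool <- dataset$M * dataset$class_fractions[[cl]]
    n_cl <- sum(obs == cl)
    if (n_cl > pool + 1e-9)
      stop("class '", cl, "' has more observed colonists than mainland pool ",
           "species", call. = FALSE)
    ll0 <- if (auto)
      loglik_record_once(empty_rec, params_by_class[[cl]],
                         dataset$island_age,
                         n_max_mult * default_n_max(empty_rec,
                                                    params_by_class[[cl]]),
                         engine)
    else loglik_colonist(empty_rec, params_by_class[[cl]],
                         dataset$island_age, n_max = n_max, engine = engine)
    ll <- ll + (pool - n_cl) * ll0
    if (condition) {
      # P(island non-empty) = 1 - prod_classes P(no descendants)^pool
      if (cl == classes[[1]]) p_empty_log <- 0
      p_empty_log <- p_empty_log + pool * ll0
      if (cl == classes[[length(classes)]])
        ll <- ll - log1p(-exp(p_empty_log))
    }
  }
  ll
}
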