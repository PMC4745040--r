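#' Simulate island assembly forwards in time
#'
#' Exact continuous-time (Gillespie) simulation of the assembly process over
#' the island's life span.  Every mainland-pool species is simulated
#' independently: it immigrates at the diversity-dependent rate
#' `gamma_N`; island species go extinct at `mu`, split at `lambda_c_N`, and
#' the non-endemic population anagenetically becomes endemic at `lambda_a`.
#' A re-immigration onto a still-conspecific population resets its
#' colonisation time (the later immigrant replaces the earlier one).
#'
#' @param params_by_class named list of [parameter_set()] (one per class), or
#'   a single `parameter_set` for a one-class pool.
#' @param M mainland pool size.
#' @param class_fractions named fractions of the pool per class (sum to 1).
#' @param island_age island age (My); the simulation runs from island birth
#'   (forward time 0) to the present (`island_age`).
#' @param seed optional integer seed.
#' @param dtt_points number of equally spaced time points at which the
#'   diversity-through-time trajectory is recorded (default 1000).
#' @return an object of class `sim_outcome` with elements
#'   `lineages` (per-colonising-mainland-species event logs and species
#'   tables), `events` (combined time-ordered event log), `dtt`
#'   (diversity-through-time on the fixed grid), and `dataset` (the
#'   [island_dataset()] implied by the present-day survivors).
#' @export
#' @examples
#' p <- parameter_set(0.05, 0.3, 1, 0.1)
#' out <- simulate_island(list(all = p), M = 100, c(all = 1), island_age = 4,
#'                        seed = 1)
#' out$dataset
simulate_island <- function(params_by_class, M, class_fractions = c(all = 1),
                            island_age, seed = NULL, dtt_points = 1000L) {
  if (inherits(params_by_class, "parameter_set"))
    params_by_class <- setNames(rep(list(params_by_class),
                                    length(class_fractions)),
                                names(class_fractions))
  if (!is.null(seed)) set.seed(seed)
  stopifnot(abs(sum(class_fractions) - 1) < 1e-8, island_age > 0)
  classes <- names(class_fractions)
  lineages <- list()
  for (cl in classes) {
    p <- params_by_class[[cl]]
    if (is.null(p)) stop("no parameters for class ", cl, call. = FALSE)
    Mc <- round(M * class_fractions[[cl]])
    sims <- .cpp_sim_class(p$gamma, p$lambda_c, p$lambda_a, p$mu, p$K_prime,
                           island_age, Mc)
    sims <- lapply(sims, function(s) { s$class <- cl; s })
    lineages <- c(lineages, sims)
  }
  ev <- combine_events(lineages)
  grid <- seq(0, island_age, length.out = dtt_points)
  dtt <- replay_dtt(ev, grid)
  ds <- outcome_dataset(lineages, island_age, M, class_fractions)
  structure(list(lineages = lineages, events = ev,
                 dtt = data.frame(time = grid, n_species = dtt),
                 dataset = ds, island_age = island_age, M = M,
                 class_fractions = class_fractions),
            class = "sim_outcome")
}

#' @export
print.sim_outcome <- function(x, ...) {
  cat("island assembly simulation: age", x$island_age, "My, M =", x$M, "\n",
      nrow(x$events), "events,", utils::tail(x$dtt$n_species, 1),
      "extant species,", length(x$dataset$colonists),
      "surviving colonisations\n")
  invisible(x)
}

combine_events <- function(lineages) {
  if (!length(lineages))
    return(data.frame(t = numeric(), code = integer(), delta = integer(),
                      type = character(), class = character(),
                      mainland_id = integer(), stringsAsFactors = FALSE))
  nper <- vapply(lineages, function(l) length(l$events$t), integer(1))
  ev <- data.frame(
    t = unlist(lapply(lineages, function(l) l$events$t)),
    code = unlist(lapply(lineages, function(l) l$events$code)),
    delta = unlist(lapply(lineages, function(l) l$events$delta)),
    class = rep(vapply(lineages, `[[`, "", "class"), nper),
    mainland_id = rep(vapply(lineages, function(l)
      as.integer(l$mainland_id), integer(1)), nper),
    stringsAsFactors = FALSE)
  ev$type <- c("immigration", "reimmigration", "cladogenesis", "anagenesis",
               "extinction")[ev$code]
  ev[order(ev$t), , drop = FALSE]
}

replay_dtt <- function(events, grid) {
  if (!nrow(events)) return(rep(0L, length(grid)))
  counts <- cumsum(events$delta)
  idx <- findInterval(grid, events$t)
  ifelse(idx == 0L, 0L, counts[pmax(idx, 1L)])
}

# survivor analysis of one per-mainland-species simulation; returns a
# colonist_record or NULL when nothing survives to the present
lineage_to_record <- function(lin, island_age) {
  sp <- lin$species
  n <- length(sp$parent)
  alive <- is.na(sp$t_death)
  if (!any(alive)) return(NULL)
  # survivor counts per node and root membership; parents precede children
  cnt <- as.integer(alive)
  for (i in rev(seq_len(n)))
    if (!is.na(sp$parent[i]))
      cnt[sp$parent[i]] <- cnt[sp$parent[i]] + cnt[i]
  root <- integer(n)
  for (i in seq_len(n))
    root[i] <- if (is.na(sp$parent[i])) i else root[sp$parent[i]]
  pop <- which(alive & sp$endemic == 0L)  # at most one
  end_alive <- which(alive & sp$endemic == 1L)
  lab <- sprintf("%s-%d", lin$class, lin$mainland_id)
  if (!length(end_alive)) {
    return(colonist_record(lab, 3L, island_age - sp$t_col[pop],
                           lineage_class = lin$class))
  }
  eroots <- unique(root[end_alive])
  primary <- eroots[which.min(sp$t_col[eroots])]
  n_missing <- sum(!root[end_alive] %in% primary)
  in_primary <- root == primary
  nodes <- which(in_primary & !is.na(sp$child1))
  keep <- nodes[cnt[sp$child1[nodes]] > 0 & cnt[sp$child2[nodes]] > 0]
  bt <- island_age - sp$t_death[keep]
  colonist_record(lab, if (length(pop)) 5L else 4L,
                  island_age - sp$t_col[primary],
                  sort(bt, decreasing = TRUE), n_missing = n_missing,
                  lineage_class = lin$class)
}

outcome_dataset <- function(lineages, island_age, M, class_fractions) {
  recs <- Filter(Negate(is.null),
                 lapply(lineages, lineage_to_record,
                        island_age = island_age))
  island_dataset(island_age, M, recs, class_fractions)
}

#' Simulate an ensemble of islands with optional conditioning
#'
#' Repeats [simulate_island()] until `n_replicates` outcomes satisfy the
#' acceptance predicate (none by default), and summarises the
#' diversity-through-time trajectories by pointwise percentiles.
#'
#' @inheritParams simulate_island
#' @param n_replicates number of accepted replicates.
#' @param condition `NULL`, or a predicate `function(outcome)`; rejected
#'   outcomes are discarded and re-drawn.
#' @param probs percentiles of the pointwise diversity-through-time band;
#'   the headline figure uses the 2.5th and 75th percentiles around the
#'   median, but both tails are configurable.
#' @param max_attempts attempt cap before aborting with the empirical
#'   acceptance rate.
#' @return an object of class `sim_ensemble`: `outcomes` (list), `dtt_bands`
#'   (data.frame: time, one column per percentile, and the median),
#'   `acceptance_rate`, `n_attempts`.
#' @export
simulate_ensemble <- function(params_by_class, M, class_fractions = c(all = 1),
                              island_age, n_replicates, condition = NULL,
                              probs = c(0.025, 0.75), seed = NULL,
                              max_attempts = 100L * n_replicates,
                              dtt_points = 1000L) {
  stopifnot(n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  outcomes <- vector("list", n_replicates)
  got <- 0L; tried <- 0L
  while (got < n_replicates) {
    if (tried >= max_attempts)
      stop("conditioning predicate accepted ", got, "/", tried,
           " replicates (acceptance rate ", signif(got / tried, 3),
           "); giving up after ", max_attempts, " attempts", call. = FALSE)
    out <- simulate_island(params_by_class, M, class_fractions, island_age,
                           dtt_points = dtt_points)
    tried <- tried + 1L
    if (is.null(condition) || isTRUE(condition(out))) {
      got <- got + 1L
      outcomes[[got]] <- out
    }
  }
  dtt <- vapply(outcomes, function(o) o$dtt$n_species,
                numeric(dtt_points))
  grid <- outcomes[[1]]$dtt$time
  bands <- data.frame(time = grid,
                      median = apply(dtt, 1, median))
  for (p in probs)
    bands[[sprintf("p%g", 100 * p)]] <- apply(dtt, 1, quantile, probs = p)
  structure(list(outcomes = outcomes, dtt_bands = bands,
                 acceptance_rate = got / tried, n_attempts = tried),
            class = "sim_ensemble")
}

#' Conditioning predicate: a given number of colonisations of one class
#'
#' Builds an acceptance predicate for [simulate_ensemble()], e.g. exactly
#' one surviving colonisation of the radiation-prone class.  `scope`
#' chooses between colonisations surviving to the present (default) and
#' colonisation events that ever happened.
#'
#' @param class lineage-class label.
#' @param n required number of colonisations (default 1).
#' @param scope `"surviving"` or `"ever"`.
#' @param comparison `"exactly"` (default) or `"at_least"`.
#' @return a predicate `function(outcome)`.
#' @export
condition_n_colonisations <- function(class, n = 1L,
                                      scope = c("surviving", "ever"),
                                      comparison = c("exactly", "at_least")) {
  scope <- match.arg(scope)
  comparison <- match.arg(comparison)
  function(outcome) {
    got <- if (scope == "surviving") {
      cls <- vapply(outcome$dataset$colonists, `[[`, "", "lineage_class")
      sum(cls == class)
    } else {
      ev <- outcome$events
      sum(ev$class == class & ev$type == "immigration")
    }
    if (comparison == "exactly") got == n else got >= n
  }
}

#' Colonisation ages of extant, not-yet-speciated lineages
#'
#' Collects, across an ensemble, the colonisation times of lineages of one
#' class that are present on the island at the end of the simulation but
#' have not yet speciated (non-endemic populations; the
#' most-recent-immigration convention applies).
#'
#' @param ensemble a [simulate_ensemble()] result (or plain list of
#'   [simulate_island()] outcomes).
#' @param class lineage-class label.
#' @param probs percentiles reported alongside the median.
#' @return a list: `ages` (vector, My before present), `median`,
#'   `percentiles`, `n`, and `empty` flag when no lineage qualifies.
#' @export
colonisation_age_distribution <- function(ensemble, class,
                                          probs = c(0.025, 0.975)) {
  outs <- if (inherits(ensemble, "sim_ensemble")) ensemble$outcomes
          else ensemble
  if (!length(outs)) stop("empty ensemble", call. = FALSE)
  ages <- unlist(lapply(outs, function(o) {
    recs <- o$dataset$colonists
    keep <- vapply(recs, function(r)
      r$lineage_class == class && r$status %in% c(2L, 3L), logical(1))
    vapply(recs[keep], `[[`, numeric(1), "colonisation_time")
  }))
  if (!length(ages))
    return(list(ages = numeric(), median = NA_real_,
                percentiles = setNames(rep(NA_real_, length(probs)),
                                       sprintf("p%g", 100 * probs)),
                n = 0L, empty = TRUE))
  list(ages = ages, median = median(ages),
       percentiles = setNames(quantile(ages, probs), sprintf("p%g",
                                                             100 * probs)),
       n = length(ages), empty = FALSE)
}

#' Present-day summary statistics of a simulated island
#'
#' Deterministic recount of the realised island state: total species,
#' per-class species, surviving colonisation events, endemic clades,
#' non-endemic lineages and anagenetic species.
#'
#' @param outcome a [simulate_island()] result.
#' @return an object of class `summary_statistics` (a named list of counts).
#' @export
summarise_outcome <- function(outcome) {
  recs <- outcome$dataset$colonists
  st <- vapply(recs, `[[`, integer(1), "status")
  cls <- vapply(recs, `[[`, "", "lineage_class")
  nsp <- vapply(recs, record_n_species, integer(1))
  n_ana <- sum(vapply(outcome$lineages, function(l) {
    sp <- l$species
    sum(is.na(sp$t_death) & sp$endemic == 1L & sp$origin == 2L)
  }, numeric(1)))
  per_class <- vapply(names(outcome$class_fractions),
                      function(cl) sum(nsp[cls == cl]), numeric(1))
  structure(list(
    total_species = sum(nsp),
    per_class_species = per_class,
    n_colonisations = length(recs),
    n_endemic_clades = sum(st %in% c(4L, 5L)),
    n_nonendemic_lineages = sum(st %in% c(2L, 3L, 5L)),
    n_anagenetic_species = n_ana), class = "summary_statistics")
}

#' @export
print.summary_statistics <- function(x, ...) {
  cat("present-day island summary:\n")
  cat("  total species        ", x$total_species, "\n")
  for (cl in names(x$per_class_species))
    cat(sprintf("    %-19s %d\n", cl, x$per_class_species[[cl]]))
  cat("  colonisation events  ", x$n_colonisations, "\n")
  cat("  endemic clades       ", x$n_endemic_clades, "\n")
  cat("  non-endemic lineages ", x$n_nonendemic_lineages, "\n")
  cat("  anagenetic species   ", x$n_anagenetic_species, "\n")
  invisible(x)
}
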