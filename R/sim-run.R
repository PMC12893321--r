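# Rolling-relabel window: twice the IBD age below which ~90% of autozygous
# tracts still exceed the 500 kb ROH threshold, in years.
default_roh_window <- function(layout, generation_years = 10) {
  r_bp <- layout$intergene_crossover_prob / layout$intergenic_length
  g90 <- 2.3 / (2 * r_bp * 5e5)
  w <- max(200, round(2 * g90 * generation_years))
  w + w %% 2
}

#' Run a demographic scenario in the forward simulator
#'
#' Simulates the individual-based non-Wright-Fisher model year by year
#' through the scenario's epochs (and lineage split, if any), recording a
#' trajectory of population size, ROH-based inbreeding (F_ROH at the 500 kb
#' and 1 Mb thresholds, from exact founder-ancestry autozygosity), and
#' realized/masked genetic load per deleterious class. Extinction before the
#' scenario end truncates the trajectory and sets the `extinct` flag (it is
#' not an error).
#'
#' @param scenario a [demographic_scenario()].
#' @param layout a [genome_layout()].
#' @param dfe a [dfe_config()].
#' @param life a [life_history()].
#' @param seed integer seed (all randomness derives from it).
#' @param record_every record the trajectory every this many years
#'   (default 10).
#' @param roh_subsample per-record random subsample of individuals used for
#'   the per-individual statistics (default 50; 0 = everyone).
#' @param roh_window rolling ancestry-relabel window in years for the
#'   autozygosity tracker (two staggered label layers; F_ROH is measured on
#'   labels at least half a window old). Default `NULL` chooses ~2x the age
#'   below which IBD segments still exceed the 500 kb threshold, from the
#'   layout's recombination rate.
#' @return Object of class `sim_trajectory`: list with `trajectory` (data
#'   frame), `population` (serialized end state usable as a [run_pva()]
#'   start), `extinct`, `extinction_year`, `epoch_end_years`, and the
#'   configuration objects.
#' @export
run_scenario <- function(scenario, layout = genome_layout(),
                         dfe = dfe_config(), life = life_history(),
                         seed = 1L, record_every = 10L,
                         roh_subsample = 50L, roh_window = NULL) {
  stopifnot(inherits(scenario, "demographic_scenario"),
            inherits(layout, "genome_layout"))
  roh_window <- roh_window %||% default_roh_window(layout)
  sc <- list(durations = as.integer(scenario$epochs$duration_years),
             K0 = as.numeric(scenario$epochs$K_start),
             K1 = as.numeric(scenario$epochs$K_end),
             split_duration = if (is.null(scenario$split)) 0L
                              else as.integer(scenario$split$duration),
             K_A = if (is.null(scenario$split)) 0 else scenario$split$K_A,
             K_B = if (is.null(scenario$split)) 0 else scenario$split$K_B,
             K_A_start = if (is.null(scenario$split)) 0 else
               scenario$split$K_A_start %||% scenario$split$K_A,
             K_B_start = if (is.null(scenario$split)) 0 else
               scenario$split$K_B_start %||% scenario$split$K_B)
  res <- with_seed(seed, cpp_run_scenario(unclass(layout), unclass(dfe),
                                          unclass(life), sc,
                                          as.integer(record_every),
                                          as.integer(roh_subsample),
                                          as.integer(roh_window)))
  structure(c(res, list(scenario = scenario, layout = layout, dfe = dfe,
                        life = life, seed = seed)),
            class = "sim_trajectory")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf(
    "sim_trajectory '%s': %d records over %d years, final N = %d%s\n",
    x$scenario$label, nrow(tr), max(tr$year), tail(tr$N, 1),
    if (x$extinct) sprintf(" (EXTINCT in year %d)", x$extinction_year)
    else ""))
  invisible(x)
}

#' Allele frequencies of segregating mutations in a saved population
#'
#' @param population the serialized `population` element of a
#'   [run_scenario()] / [run_pva()] result.
#' @return Data frame with `id`, `gene`, `s`, `class`, `count`, `freq`
#'   (frequency among the 2N haplotypes) for mutations at frequency > 0.
#' @export
pop_mutation_freqs <- function(population) {
  n_hap <- 2L * length(population$id)
  if (n_hap == 0L) stop_hylopop("population is extinct")
  ids <- c(unlist(population$h1), unlist(population$h2))
  cnt <- tabulate(ids + 1L, nbins = length(population$mut_gene))
  seg <- which(cnt > 0L)
  data.frame(id = seg - 1L,
             gene = population$mut_gene[seg],
             s = population$mut_s[seg],
             class = factor(
               mutation_class_labels()[population$mut_cls[seg] + 1L],
               levels = mutation_class_labels()),
             count = cnt[seg],
             freq = cnt[seg] / n_hap)
}

#' Continue a saved population forward under constant conditions
#'
#' Runs the same yearly life cycle as [run_scenario()] from a saved
#' population at a constant carrying capacity, optionally under a
#' lineage-cross mating constraint. This is the engine behind [run_pva()]
#' and is also useful for neutral drift checks.
#'
#' @param population serialized population (from [run_scenario()] or a
#'   previous call).
#' @param years years to simulate.
#' @param K carrying capacity.
#' @param mating `"random"`, `"all_cross"` or `"half_cross"`.
#' @param K2 `NULL` (default): merge everyone into one habitat at capacity
#'   `K`; otherwise keep subpopulations 0 and 1 separate at capacities `K`
#'   and `K2`.
#' @inheritParams run_scenario
#' @param return_population include the end-state population.
#' @return List with `trajectory`, `extinct`, `extinction_year` (years since
#'   the start of this continuation) and optionally `population`.
#' @export
continue_population <- function(population, years, K, K2 = NULL,
                                mating = c("random", "all_cross",
                                           "half_cross"),
                                layout = genome_layout(),
                                dfe = dfe_config(), life = life_history(),
                                seed = NULL, record_every = 10L,
                                roh_subsample = 50L, roh_window = NULL,
                                return_population = TRUE) {
  mating <- match.arg(mating)
  roh_window <- roh_window %||% default_roh_window(layout)
  with_seed(seed,
    cpp_run_forward(population, unclass(layout), unclass(dfe),
                    unclass(life), mating, as.numeric(K),
                    if (is.null(K2)) -1 else as.numeric(K2),
                    as.integer(years), as.integer(record_every),
                    as.integer(roh_subsample), as.integer(roh_window),
                    return_population))
}

#' Split a population into two lineages and simulate the isolation period
#'
#' Randomly partitions a saved population into lineages A and B (each
#' individual assigned with probability K_A / (K_A + K_B) to A), labels
#' their ancestry, and simulates `duration` years of complete isolation at
#' the two carrying capacities. Either or both lineages may drift to
#' extinction during the isolation; check the returned population's lineage
#' labels before using it as a PVA start (see `both_lineages_alive()`).
#'
#' @param population serialized population (e.g. the `population_presplit`
#'   element of a [run_scenario()] result).
#' @param K_A,K_B lineage carrying capacities (defaults 6 and 5).
#' @param duration years of isolation (default 450).
#' @inheritParams continue_population
#' @return As [continue_population()], with `population` carrying lineage
#'   ancestry labels (admix 1 = pure A, 0 = pure B).
#' @export
split_lineages <- function(population, K_A = 6, K_B = 5, duration = 450,
                           K_A_start = NULL, K_B_start = NULL,
                           layout = genome_layout(), dfe = dfe_config(),
                           life = life_history(), seed = NULL,
                           record_every = 50L, roh_subsample = 50L,
                           roh_window = NULL) {
  roh_window <- roh_window %||% default_roh_window(layout)
  K_A_start <- K_A_start %||% K_A
  K_B_start <- K_B_start %||% K_B
  with_seed(seed, {
    to_a <- runif(length(population$id)) < K_A_start / (K_A_start + K_B_start)
    population$subpop <- ifelse(to_a, 0L, 1L)
    population$admix <- ifelse(to_a, 1, 0)
    res <- NULL
    steps <- max(1L, as.integer(duration %/% 50))
    pop <- population
    tra <- NULL
    for (st in seq_len(steps)) {
      yr0 <- round((st - 1) * duration / steps)
      yr1 <- round(st * duration / steps)
      f <- yr1 / duration
      ka <- K_A_start + (K_A - K_A_start) * f
      kb <- K_B_start + (K_B - K_B_start) * f
      res <- cpp_run_forward(pop, unclass(layout), unclass(dfe),
                             unclass(life), "random", ka, kb,
                             as.integer(yr1 - yr0),
                             as.integer(record_every),
                             as.integer(roh_subsample),
                             as.integer(roh_window), TRUE)
      pop <- res$population
      tra <- if (is.null(tra)) res$trajectory
             else rbind(tra, res$trajectory[-1, ])
      if (res$extinct) break
    }
    res$trajectory <- tra
    res
  })
}

#' Do both lineages survive in a saved population?
#'
#' @param population serialized population with lineage ancestry labels.
#' @return `TRUE` if at least one pure lineage-A and one pure lineage-B
#'   individual are alive.
#' @export
both_lineages_alive <- function(population) {
  length(population$id) > 0 && any(population$admix == 1) &&
    any(population$admix == 0)
}

#' Is a saved population a viable PVA starting point?
#'
#' The lineage-cross viability analysis presupposes a present-day population
#' in which both lineages persist and new breeding pairs can still form (as
#' observed in the real population, where mixed-lineage family groups were
#' established). This requires, beyond [both_lineages_alive()], at least one
#' male and one female young enough to breed in the future.
#'
#' @param population serialized population with lineage ancestry labels.
#' @param max_breedable_age oldest age counted as a prospective breeder
#'   (default 35).
#' @return Logical.
#' @export
pva_start_viable <- function(population, max_breedable_age = 35) {
  both_lineages_alive(population) &&
    any(population$sex == 1 & population$age <= max_breedable_age) &&
    any(population$sex == 0 & population$age <= max_breedable_age)
}

#' Population viability analysis under lineage-cross mating scenarios
#'
#' Projects a starting population (typically the end state of the gibbon
#' demographic scenario, carrying lineage labels A/B from the split) forward
#' for `generations` generations at carrying capacity `K`, replicated
#' `n_replicates` times, under one of three mate-choice regimes:
#' `"all_cross"` (every new pair bond must join individuals of different
#' lineage ancestry), `"half_cross"` (each pairing is constrained
#' inter-lineage with probability 0.5), or `"random"` (unconstrained).
#' Admixed individuals count as inter-lineage partners for anyone; offspring
#' ancestry is the parental mean. Reported per replicate: extinction, and
#' per-generation population size and mean F_ROH (>= 500 kb).
#'
#' @param start_pop a serialized population, or a list of them (replicates
#'   cycle over the list, so independent burn-ins can be supplied).
#' @param scenario `"all_cross"`, `"half_cross"` or `"random"`.
#' @param n_replicates number of replicates (default 200).
#' @param generations projection horizon in generations (default 100).
#' @param K carrying capacity during the projection (default 2000; pass a
#'   scaled value for scaled layouts).
#' @param generation_years years per generation (default 10).
#' @inheritParams run_scenario
#' @return Object of class `pva_result`: `scenario`, `n_replicates`,
#'   `extinction_rate`, `extinct` (logical per replicate), `size_trajectories`
#'   and `froh_trajectories` (generation x replicate matrices, `NA` after
#'   extinction).
#' @export
run_pva <- function(start_pop, scenario = c("all_cross", "half_cross",
                                            "random"),
                    n_replicates = 200L, generations = 100L, K = 2000,
                    generation_years = 10L, layout = genome_layout(),
                    dfe = dfe_config(), life = life_history(), seed = 1L,
                    roh_subsample = 30L, roh_window = NULL) {
  scenario <- match.arg(scenario)
  roh_window <- roh_window %||% default_roh_window(layout)
  assert_count(n_replicates, "n_replicates")
  pops <- if (!is.null(start_pop$id)) list(start_pop) else start_pop
  if (scenario != "random") {
    adm <- unlist(lapply(pops, function(p) p$admix))
    if (!any(adm == 1) || !any(adm == 0))
      stop_hylopop(sprintf(
        "start population lacks both lineages; cannot run '%s'", scenario))
  }
  years <- as.integer(generations) * as.integer(generation_years)
  gens <- seq_len(generations)
  size_m <- matrix(NA_real_, nrow = generations, ncol = n_replicates)
  froh_m <- matrix(NA_real_, nrow = generations, ncol = n_replicates)
  extinct <- logical(n_replicates)
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      p0 <- pops[[((r - 1L) %% length(pops)) + 1L]]
      res <- cpp_run_forward(p0, unclass(layout), unclass(dfe),
                             unclass(life), scenario, as.numeric(K), -1,
                             years, as.integer(generation_years),
                             as.integer(roh_subsample),
                             as.integer(roh_window), FALSE)
      tr <- res$trajectory
      # records at multiples of generation_years; row 1 is the start state
      gen_rows <- match(gens * generation_years,
                        tr$year - tr$year[1])
      size_m[, r] <- tr$N[gen_rows]
      froh_m[, r] <- tr$froh500[gen_rows]
      extinct[r] <- res$extinct
      if (res$extinct) {
        gone <- gens * generation_years > res$extinction_year
        size_m[gone, r] <- 0
      }
    }
  })
  structure(list(scenario = scenario, n_replicates = n_replicates,
                 extinction_rate = mean(extinct), extinct = extinct,
                 size_trajectories = size_m, froh_trajectories = froh_m,
                 generations = generations, K = K),
            class = "pva_result")
}

#' @export
print.pva_result <- function(x, ...) {
  cat(sprintf(
    "pva_result '%s': %d replicates x %d generations (K = %g)\n  extinction rate %.3f\n",
    x$scenario, x$n_replicates, x$generations, x$K, x$extinction_rate))
  invisible(x)
}

#' Compare PVA scenarios with paired nonparametric tests
#'
#' For each pair of PVA results (equal replicate counts, matched replicate
#' structure), computes Wilcoxon signed-rank tests on per-replicate mean
#' F_ROH and mean population size over the projection, per-generation
#' signed-rank statistics, and the extinction-rate contrast with exact
#' binomial confidence intervals.
#'
#' @param results named list of [run_pva()] results.
#' @param conf_level confidence level for the binomial CIs (default 0.95).
#' @return List with `extinction` (data frame: scenario, rate, CI) and
#'   `pairwise` (data frame per scenario pair: signed-rank p-values for
#'   inbreeding and size, and the median paired differences).
#' @export
compare_scenarios <- function(results, conf_level = 0.95) {
  stopifnot(is.list(results), length(results) >= 2L)
  if (is.null(names(results)))
    names(results) <- vapply(results, function(r) r$scenario, character(1))
  nreps <- vapply(results, function(r) r$n_replicates, numeric(1))
  if (length(unique(nreps)) != 1L)
    stop_hylopop("replicate counts differ between scenarios; comparisons must be matched")
  gens <- vapply(results, function(r) r$generations, numeric(1))
  if (length(unique(gens)) != 1L)
    stop_hylopop("projection horizons differ between scenarios")
  ext <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    ci <- stats::binom.test(sum(r$extinct), r$n_replicates,
                            conf.level = conf_level)$conf.int
    data.frame(scenario = nm, extinction_rate = r$extinction_rate,
               ci_lo = ci[1], ci_hi = ci[2])
  }))
  rep_mean <- function(m) colMeans(m, na.rm = TRUE)
  pairs <- utils::combn(names(results), 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    a <- results[[pr[1]]]; b <- results[[pr[2]]]
    fa <- rep_mean(a$froh_trajectories); fb <- rep_mean(b$froh_trajectories)
    na_ <- rep_mean(a$size_trajectories); nb <- rep_mean(b$size_trajectories)
    wt <- function(x, y) {
      d <- x - y
      d <- d[is.finite(d)]
      if (!length(d) || all(d == 0)) return(list(p = NA_real_, med = 0))
      ht <- suppressWarnings(wilcox.test(d))
      list(p = ht$p.value, med = median(d))
    }
    f <- wt(fa, fb); n <- wt(na_, nb)
    data.frame(a = pr[1], b = pr[2],
               froh_p = f$p, froh_median_diff = f$med,
               size_p = n$p, size_median_diff = n$med)
  }))
  list(extinction = ext, pairwise = pw)
}
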