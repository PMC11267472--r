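# End-to-end simulators of the two selection designs: the single-generation
# extreme (xQTL) design — fastest maters vs random males pooled and
# sequenced — and the multi-generation truncation-selection experiment with
# contemporaneous unselected controls.

# assay a cohort of males and return trials plus overall proportion mated
.assay_males <- function(cohort, panel, model, window,
                         observe_beyond_window = FALSE) {
  males <- subset_population(cohort, which(cohort$sex == "M"))
  lia <- mating_liability(males, panel, model)
  trials <- simulate_mating_assay(liability_hazard(lia, model),
                                  window = window,
                                  observe_beyond_window = observe_beyond_window)
  list(males = males, trials = trials,
       proportion = sum(trials$mated) / sum(tapply(trials$n_females,
                                                   trials$vial, max)))
}

#' Simulate the single-generation extreme (xQTL) selection design
#'
#' For each biological replicate, `n_assayed` males bred from the
#' intercross population are assayed with tester females, the `k` fastest
#' maters form a high pool and `k` random males a control pool, and both
#' pools are sequenced at the given coverage.
#'
#' @param aip An intercross `population` (see [build_aip()]).
#' @param panel The originating `founder_panel`.
#' @param model A `trait_model`.
#' @param n_replicates Biological replicates per group.
#' @param n_assayed Males assayed per replicate.
#' @param k Pool size (fastest maters / random males).
#' @param window Assay window, minutes.
#' @param coverage Mean sequencing depth per pool.
#' @param seed Optional RNG seed.
#' @return List: high, control (lists of `pool_counts`), proportions
#'   (mated fraction per replicate).
#' @export
simulate_xqtl_experiment <- function(aip, panel, model, n_replicates = 4,
                                     n_assayed = 500, k = 50, window = 60,
                                     coverage = 100, seed = NULL) {
  with_seed(seed, {
    high <- control <- vector("list", n_replicates)
    props <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      cohort <- breed_cohort(aip, panel, n_female = 0, n_male = n_assayed)
      as <- .assay_males(cohort, panel, model, window,
                        observe_beyond_window = TRUE)
      props[r] <- as$proportion
      hi_ids <- truncation_select(as$trials, "k_fastest", k)
      rn_ids <- truncation_select(as$trials, "k_random", k)
      high[[r]] <- simulate_pool_seq(subset_population(as$males, hi_ids),
                                     panel, coverage,
                                     pool_id = sprintf("high_%d", r))
      control[[r]] <- simulate_pool_seq(subset_population(as$males, rn_ids),
                                        panel, coverage,
                                        pool_id = sprintf("control_%d", r))
    }
    list(high = high, control = control, proportions = props)
  })
}

#' Simulate the multi-generation truncation-selection experiment
#'
#' Each selected replicate assays `n_assayed_sel` males per generation and
#' breeds the first `k` to mate with the tester females to `k` random
#' sibling females; control populations assay males the same way but
#' breed `k` random males.  A second control is split off from the first
#' at `control2_start`.  Per-generation mated proportions are recorded
#' for every population, in the layout [deviation_trajectory()] consumes.
#'
#' @param aip Starting intercross `population`.
#' @param panel The originating `founder_panel`.
#' @param model A `trait_model`.
#' @param generations Selection generations after generation 0.
#' @param n_replicates Selected replicate lines.
#' @param n_assayed_sel Males assayed per selected line per generation.
#' @param n_assayed_ctrl Males assayed per control line per generation.
#' @param k Males (and females) bred per line per generation.
#' @param window Assay window, minutes.
#' @param control2_start Generation at which the second control line is
#'   split from the first (NULL for a single control).
#' @param seed Optional RNG seed.
#' @return List: selected, control (data.frames generation, replicate,
#'   proportion), populations (final breeding populations per line).
#' @export
simulate_selection_experiment <- function(aip, panel, model,
                                          generations = 18,
                                          n_replicates = 2,
                                          n_assayed_sel = 300,
                                          n_assayed_ctrl = 150,
                                          k = 40, window = 60,
                                          control2_start = 5,
                                          seed = NULL) {
  with_seed(seed, {
    sel_rows <- ctl_rows <- list()
    # generation-0 parents drawn from the AIP for each line
    draw_parents <- function() {
      fem <- sample(which(aip$sex == "F"), k)
      mal <- sample(which(aip$sex == "M"), k)
      subset_population(aip, c(fem, mal))
    }
    sel_par <- replicate(n_replicates, draw_parents(), simplify = FALSE)
    ctl_par <- list(draw_parents())

    step <- function(parents, n_assayed, rule) {
      cohort <- breed_cohort(parents, panel, n_female = k,
                             n_male = n_assayed)
      as <- .assay_males(cohort, panel, model, window,
                        observe_beyond_window = TRUE)
      ids <- truncation_select(as$trials, rule, k)
      females <- subset_population(cohort, which(cohort$sex == "F"))
      males <- subset_population(as$males, ids)
      list(parents = bind_populations(females, males),
           proportion = as$proportion)
    }

    for (g in 0:generations) {
      for (r in seq_len(n_replicates)) {
        st <- step(sel_par[[r]], n_assayed_sel, "first_k")
        sel_par[[r]] <- st$parents
        sel_rows[[length(sel_rows) + 1L]] <-
          data.frame(generation = g, replicate = r,
                     proportion = st$proportion)
      }
      if (!is.null(control2_start) && g == control2_start)
        ctl_par[[2]] <- ctl_par[[1]]
      for (cr in seq_along(ctl_par)) {
        n_c <- if (g == 0) n_assayed_sel else n_assayed_ctrl
        st <- step(ctl_par[[cr]], n_c, "k_random")
        ctl_par[[cr]] <- st$parents
        ctl_rows[[length(ctl_rows) + 1L]] <-
          data.frame(generation = g, replicate = cr,
                     proportion = st$proportion)
      }
    }
    list(selected = do.call(rbind, sel_rows),
         control = do.call(rbind, ctl_rows),
         populations = list(selected = sel_par, control = ctl_par))
  })
}
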