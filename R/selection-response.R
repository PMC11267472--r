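# Phenotypic analysis of multi-generation selection: deviations of
# selected replicates from contemporaneous controls and the OLS response
# regression on generation number.

#' Deviations of selected lines from contemporaneous controls
#'
#' The control mean at each generation averages over however many control
#' populations exist there (a second control line may join partway
#' through); each selected replicate's deviation is its proportion minus
#' that contemporaneous control mean, and the replicate-average deviation
#' series is appended.
#'
#' @param selected data.frame: generation, replicate, proportion.
#' @param control data.frame: generation, replicate, proportion (NA or
#'   absent rows for a control not yet established).
#' @return A `trajectory` list: deviations (generation, replicate,
#'   deviation), average (generation, deviation), control_mean
#'   (generation, mean), generations.
#' @export
deviation_trajectory <- function(selected, control) {
  gens <- sort(unique(selected$generation))
  ctl <- control[!is.na(control$proportion), , drop = FALSE]
  if (!all(gens %in% ctl$generation))
    stop("control series missing generations: ",
         paste(setdiff(gens, ctl$generation), collapse = ", "))
  cmean <- vapply(gens, function(g)
    mean(ctl$proportion[ctl$generation == g]), numeric(1))
  names(cmean) <- gens
  dev <- selected
  dev$deviation <- selected$proportion - cmean[as.character(selected$generation)]
  avg <- aggregate(deviation ~ generation, data = dev, FUN = mean)
  structure(list(
    deviations = dev[, c("generation", "replicate", "deviation")],
    average = avg,
    control_mean = data.frame(generation = gens, mean = cmean,
                              row.names = NULL),
    generations = gens
  ), class = "trajectory")
}

#' Response regression of deviations on generation
#'
#' Ordinary least squares of the deviation series on generation number,
#' per selected replicate and for the replicate average, with a two-sided
#' t test on the slope.
#'
#' @param traj A `trajectory` from [deviation_trajectory()].
#' @return data.frame: series, slope, intercept, p_value, n.
#' @export
response_regression <- function(traj) {
  one <- function(df, label) {
    if (length(unique(df$generation)) < 3)
      stop("need at least 3 generations for the response regression")
    fit <- lm(deviation ~ generation, data = df)
    cf <- summary(fit)$coefficients
    data.frame(series = label, slope = cf["generation", "Estimate"],
               intercept = cf["(Intercept)", "Estimate"],
               p_value = cf["generation", "Pr(>|t|)"],
               n = nrow(df), stringsAsFactors = FALSE)
  }
  reps <- split(traj$deviations, traj$deviations$replicate)
  out <- do.call(rbind, c(
    lapply(names(reps), function(r) one(reps[[r]], paste0("replicate_", r))),
    list(one(traj$average, "average"))
  ))
  rownames(out) <- NULL
  out
}
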