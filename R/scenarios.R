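# Demographic scenarios for the four genetic groups (three seep: JR, OH, KK;
# one vent: OT). All three scenarios are pure divergence/founder models with
# no migration between branches; times are in generations before present and
# sizes are diploid effective sizes.
#
# Scenario 1: the ancestral population splits at TA into a deeper-seep lineage
#   (JR+OH, size N_JRpOH) and the Kuroshima lineage (KK). A propagule of
#   N_KKP larvae from KK invades the vent basin at T3 and establishes the OT
#   group at T2 (the OT branch has size N_KKP between T2 and T3 and N_OT from
#   the present back to T2). JR and OH diverge at T1. Beyond TA the single
#   ancestral population has size N_A.
# Scenario 2: the deeper-seep lineage is ancestral. A propagule of N_AP
#   founds the KK branch at TA (KK has size N_AP between T4 and TA); KK then
#   seeds OT via N_KKP at T3 as in scenario 1; JR/OH split at T1. Beyond TA
#   the ancestral size is N_JRpOH.
# Scenario 3: the Kuroshima lineage is ancestral. A propagule of N_KKP1
#   founds the deeper-seep branch at TA (that branch has size N_KKP1 between
#   T4 and TA and N_JRpOH from T1 back to T4); a second propagule N_KKP2
#   founds OT at T3; JR/OH split at T1. Beyond TA the ancestral size is N_KK.

.all_param_names <- c("T1", "T2", "T3", "T4", "TA",
                      "N_A", "N_JRpOH", "N_JR", "N_OH", "N_KK", "N_OT",
                      "N_KKP", "N_AP", "N_KKP1", "N_KKP2")

.group_names <- c("JR", "OH", "KK", "OT")

#' Parameters used by a demographic scenario
#'
#' @param scenario_id integer in `{1, 2, 3}`
#' @return character vector of parameter names
#' @export
scenario_param_names <- function(scenario_id) {
  base <- c("T1", "T2", "T3", "N_JRpOH", "N_JR", "N_OH", "N_KK", "N_OT")
  switch(as.character(scenario_id),
    "1" = c("T1", "T2", "T3", "TA", "N_A", base[-(1:3)], "N_KKP"),
    "2" = c("T1", "T2", "T3", "T4", "TA", base[-(1:3)], "N_KKP", "N_AP"),
    "3" = c("T1", "T2", "T3", "T4", "TA", base[-(1:3)], "N_KKP1", "N_KKP2"),
    stop("unknown scenario_id: ", scenario_id)
  )
}

.time_names <- function(scenario_id) {
  if (scenario_id == 1) c("T1", "T2", "T3", "TA") else c("T1", "T2", "T3", "T4", "TA")
}

# (founder parameter, terminal size of the branch it founds) per scenario
.founder_pairs <- function(scenario_id) {
  switch(as.character(scenario_id),
    "1" = list(c("N_KKP", "N_OT")),
    "2" = list(c("N_KKP", "N_OT"), c("N_AP", "N_KK")),
    "3" = list(c("N_KKP2", "N_OT"), c("N_KKP1", "N_JRpOH"))
  )
}

#' Construct a validated demographic parameter vector
#'
#' @param scenario_id integer in `{1, 2, 3}`
#' @param ... named parameters (see [scenario_param_names()]); times in
#'   generations, sizes in diploid individuals
#' @param check_founder enforce that each founder propagule is no larger than
#'   the terminal size of the branch it founds (default `TRUE`)
#' @return an object of class `scenario_params`
#' @export
scenario_params <- function(scenario_id, ..., check_founder = TRUE) {
  scenario_id <- as.integer(scenario_id)
  if (!scenario_id %in% 1:3) stop("unknown scenario_id: ", scenario_id)
  vals <- c(...)
  needed <- scenario_param_names(scenario_id)
  missing <- setdiff(needed, names(vals))
  if (length(missing)) {
    stop("missing parameters for scenario ", scenario_id, ": ",
         paste(missing, collapse = ", "))
  }
  vals <- vals[needed]
  if (any(!is.finite(vals)) || any(vals < 1)) {
    stop("all times and sizes must be finite and >= 1")
  }
  tn <- .time_names(scenario_id)
  if (is.unsorted(vals[tn], strictly = TRUE)) {
    stop("event times must satisfy ", paste(tn, collapse = " < "))
  }
  if (check_founder) {
    for (fp in .founder_pairs(scenario_id)) {
      if (vals[fp[1]] > vals[fp[2]]) {
        stop("founder size ", fp[1], " exceeds the size of the branch it founds (",
             fp[2], ")")
      }
    }
  }
  structure(list(scenario_id = scenario_id, values = vals),
            class = "scenario_params")
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("Demographic scenario", x$scenario_id, "\n")
  print(round(x$values, 2))
  invisible(x)
}

#' Uniform prior specification for the demographic parameters
#'
#' Defaults: event times uniform on \[10, 100000\] generations with the
#' scenario's time ordering enforced by rejection; branch sizes uniform on
#' \[10, 100000\]; founder propagule sizes uniform on \[5, 1000\].
#'
#' @param bounds named list of `c(lower, upper)` per parameter; defaults
#'   filled for parameters not supplied
#' @param ordering enforce the time ordering constraint by rejection
#' @param check_founder enforce founder-size constraints by rejection
#' @return an object of class `prior_spec`
#' @export
prior_spec <- function(bounds = list(), ordering = TRUE, check_founder = TRUE) {
  def <- list()
  for (p in c("T1", "T2", "T3", "T4", "TA")) def[[p]] <- c(10, 1e5)
  for (p in c("N_A", "N_JRpOH", "N_JR", "N_OH", "N_KK", "N_OT")) def[[p]] <- c(10, 1e5)
  for (p in c("N_KKP", "N_AP", "N_KKP1", "N_KKP2")) def[[p]] <- c(5, 1000)
  for (p in names(bounds)) {
    if (!p %in% .all_param_names) stop("unknown parameter in prior bounds: ", p)
    def[[p]] <- as.numeric(bounds[[p]])
  }
  for (p in names(def)) {
    b <- def[[p]]
    if (length(b) != 2 || any(!is.finite(b)) || b[1] > b[2]) {
      stop("prior bounds for ", p, " must be finite with lower <= upper")
    }
  }
  structure(list(bounds = def, ordering = ordering,
                 check_founder = check_founder), class = "prior_spec")
}

#' Draw a demographic parameter vector from its prior
#'
#' Parameters are drawn independently from their uniform priors; draws
#' violating the time-ordering or founder-size constraints are rejected and
#' redrawn, up to `max_tries` attempts.
#'
#' @param prior a [prior_spec()]
#' @param scenario_id integer in `{1, 2, 3}`
#' @param rng_seed integer seed (or `NULL` to use the current stream)
#' @param max_tries rejection-sampling budget
#' @return a [scenario_params()] object
#' @export
draw_scenario_params <- function(prior, scenario_id, rng_seed = NULL,
                                 max_tries = 10000L) {
  stopifnot(inherits(prior, "prior_spec"))
  needed <- scenario_param_names(scenario_id)
  lo <- vapply(needed, function(p) prior$bounds[[p]][1], numeric(1))
  hi <- vapply(needed, function(p) prior$bounds[[p]][2], numeric(1))
  # degenerate (lower == upper) priors have lower > 1 checked downstream
  tn <- .time_names(scenario_id)
  ti <- match(tn, needed)
  fp <- if (prior$check_founder) .founder_pairs(scenario_id) else list()
  fi <- lapply(fp, function(x) match(x, needed))
  with_seed(rng_seed, {
    for (i in seq_len(max_tries)) {
      vals <- lo + runif(length(needed)) * (hi - lo)
      if (any(vals < 1)) next
      tv <- vals[ti]
      if (is.unsorted(tv, strictly = TRUE)) next
      ok <- TRUE
      for (ix in fi) if (vals[ix[1]] > vals[ix[2]]) { ok <- FALSE; break }
      if (!ok) next
      names(vals) <- needed
      return(scenario_params(scenario_id, vals,
                             check_founder = prior$check_founder))
    }
    stop("could not draw parameters satisfying the constraints in ",
         max_tries, " attempts (infeasible prior?)")
  })
}

# Event table for the coalescent engine. Population slots (0-based in C++):
# 1 JR, 2 OH, 3 KK, 4 OT, 5 merged deeper-seep branch (JR+OH).
.scenario_events <- function(params) {
  v <- params$values
  sizes0 <- c(v["N_JR"], v["N_OH"], v["N_KK"], v["N_OT"], v["N_JRpOH"])
  ev <- switch(as.character(params$scenario_id),
    "1" = rbind(
      c(v["T1"], 0, 0, 4),            # JR joins deeper-seep branch
      c(v["T1"], 0, 1, 4),            # OH joins deeper-seep branch
      c(v["T2"], 1, 3, v["N_KKP"]),   # OT founder bottleneck back to T3
      c(v["T3"], 0, 3, 2),            # OT propagule merges into KK
      c(v["TA"], 0, 4, 2),            # deeper-seep branch merges into KK
      c(v["TA"], 1, 2, v["N_A"])      # single ancestral population
    ),
    "2" = rbind(
      c(v["T1"], 0, 0, 4),
      c(v["T1"], 0, 1, 4),
      c(v["T2"], 1, 3, v["N_KKP"]),
      c(v["T3"], 0, 3, 2),
      c(v["T4"], 1, 2, v["N_AP"]),    # KK founder bottleneck back to TA
      c(v["TA"], 0, 2, 4)             # KK merges into ancestral deeper-seep
    ),
    "3" = rbind(
      c(v["T1"], 0, 0, 4),
      c(v["T1"], 0, 1, 4),
      c(v["T2"], 1, 3, v["N_KKP2"]),
      c(v["T3"], 0, 3, 2),
      c(v["T4"], 1, 4, v["N_KKP1"]),  # deeper-seep founder bottleneck
      c(v["TA"], 0, 4, 2)             # deeper-seep merges into ancestral KK
    )
  )
  dimnames(ev) <- NULL
  list(sizes0 = unname(sizes0), events = ev)
}

#' Diploid sample sizes per genetic group
#'
#' The default reproduces the study design: 12 (JR), 25 (OH), 21 (KK) and
#' 63 (OT) diploid individuals.
#'
#' @param JR,OH,KK,OT diploid sample sizes (each at least 2)
#' @return named integer vector of class `sample_config`
#' @export
sample_config <- function(JR = 12, OH = 25, KK = 21, OT = 63) {
  x <- c(JR = as.integer(JR), OH = as.integer(OH), KK = as.integer(KK),
         OT = as.integer(OT))
  if (any(x < 2)) stop("all group sample sizes must be >= 2")
  structure(x, class = "sample_config")
}
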