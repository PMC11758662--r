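# Shared fixtures and independent oracles, all built in code.

# Quick cycle constructor from named propulsion starts and durations (percent).
make_cycle <- function(starts, durs, duration_s = 2.5) {
  mat <- cbind(start = starts[LIMB_LEVELS],
               end = starts[LIMB_LEVELS] + durs[LIMB_LEVELS])
  rownames(mat) <- LIMB_LEVELS
  swim_cycle(duration_s, mat)
}

# Noiseless mean-construction lap for a category: zero-SD profile, no jitter.
mean_lap <- function(category, n_cycles = 1L, seed = 1L) {
  prof <- category_profiles(category)
  prof[grep("_sd$", names(prof))] <- 0
  cfg <- synthetic_config(jitter_sd = 0, cycles_per_lap = as.integer(n_cycles))
  generate_lap(prof, config = cfg, seed = seed)
}

mean_params <- function(category) aggregate_lap(mean_lap(category))

# Random valid cycle following the canonical propulsion sequence: random
# positive sequence delays closing the cycle, random duty factors.
random_cycle <- function() {
  dl <- stats::runif(4, 2, 50)
  dl <- dl / sum(dl) * 100
  starts <- c(LF = 0, LH = dl[1], RF = dl[1] + dl[2], RH = dl[1] + dl[2] + dl[3])
  durs <- stats::runif(4, 5, 60)
  names(durs) <- LIMB_LEVELS
  make_cycle(starts, durs)
}

# Independent signed-overlap oracle on a discretized circle: grid-count
# intersection; for disjoint arcs, the smallest forward rotation that brings
# either arc's end onto the other arc (negated).
oracle_signed_overlap <- function(a, b, step = 0.01) {
  in_arc <- function(p, arc) ((p - arc[1]) %% 100) < (arc[2] - arc[1])
  g <- seq(0, 100 - step, by = step)
  inter <- sum(in_arc(g, a) & in_arc(g, b)) * step
  if (inter > 0) return(inter)
  shifts <- seq(0, 100, by = step)
  hit <- in_arc((a[2] + shifts) %% 100, b) | in_arc((b[2] + shifts) %% 100, a)
  -min(shifts[hit])
}

# One-category-per-horse mixture table, one horse per category.
per_category_mixtures <- function(categories = CATEGORY_LEVELS) {
  do.call(rbind, lapply(seq_along(categories), function(i) {
    m <- data.frame(horse_id = sprintf("H%02d", i), stringsAsFactors = FALSE)
    for (cat in CATEGORY_LEVELS) m[[cat]] <- as.numeric(cat == categories[i])
    m
  }))
}

# Cohort with n laps per category drawn with the bundled profile SDs.
profile_cohort <- function(n_per_category, seed) {
  cfg <- synthetic_config(laps_per_horse = as.integer(n_per_category),
                          seed = seed)
  lap_parameters(generate_cohort(per_category_mixtures(), cfg))
}
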