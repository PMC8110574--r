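#!/usr/bin/env Rscript
# Stage 4: population mutation rate.  Loads the simulated read-count
# profiles, fits theta (= 4 Ne mu) and the sequencing error rate by
# profile likelihood, and converts theta into per-generation and
# per-year mutation rates under the assumed ancestral population size
# and generation time.

suppressPackageStartupMessages(library(syntevol))

profiles <- load_profiles("results/sim/profiles.tsv", min_depth = 4L)
cat(sprintf("loaded %d profiles (min depth 4)\n", nrow(profiles)))
est <- estimate_theta_ml(profiles)
print(est)
truth <- jsonlite::read_json("results/sim/truth.json")
cat(sprintf("true theta %.4g; relative error %.2f%%\n", truth$theta,
            100 * abs(est$theta - truth$theta) / truth$theta))

ne <- 112421; g <- 15
mu_g <- mu_per_generation(est$theta, ne)
mu_y <- mu_per_year(mu_g, g)
cat(sprintf("mu = %.4g /site/generation (Ne = %d); %.4g /site/year (g = %d y)\n",
            mu_g, ne, mu_y, g))

jsonlite::write_json(
  list(theta = est$theta, ci_low = est$ci_low, ci_high = est$ci_high,
       error_rate = est$error_rate, sites_used = est$sites_used,
       ne_assumed = ne, generation_time = g,
       mu_per_generation = mu_g, mu_per_year = mu_y),
  "results/popgen.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/popgen.json\n")
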