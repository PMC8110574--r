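# Population mutation rate (theta = 4*Ne*mu) from read base-count
# quartets ("site profiles"), plus heterozygosity summaries and the
# per-generation / per-year mutation-rate conversions.
#
# Likelihood model: each site is heterozygous with probability
# H = theta/(1+theta) (diploid per-site heterozygosity under the
# infinite-sites approximation), else homozygous.  Given a per-base error
# rate eps, reads at a homozygous site show the true base with probability
# 1-eps and each of the three other bases with probability eps/3; at a
# heterozygous site each read draws one of the two alleles uniformly and
# then errs the same way, so each allele base appears with probability
# (1-eps)/2 + eps/6 and each non-allele base with probability eps/3.  The
# genotype bases are identified with the most frequent observed bases
# (plug-in), the multinomial coefficient cancels between the two mixture
# components, and sites are treated as independent (composite likelihood;
# linkage is ignored for point estimation).

#' Load site profiles from a TSV of per-site base counts
#'
#' @param path TSV with columns `chromosome`, `position`, `nA`, `nC`,
#'   `nG`, `nT` (header optional; detected from the first line).
#' @param min_depth Minimum coverage; profiles with total count below this
#'   are excluded (default 4, the minimum-depth rule for homozygous
#'   profile positions).
#' @return `data.frame` of validated profiles with a `coverage` column.
#' @export
load_profiles <- function(path, min_depth = 4L) {
  first <- readLines(path, n = 1L)
  if (!length(first))
    return(data.frame(chromosome = character(), position = numeric(),
                      nA = integer(), nC = integer(), nG = integer(),
                      nT = integer(), coverage = integer(),
                      stringsAsFactors = FALSE))
  has_header <- grepl("chrom", strsplit(first, "\t")[[1L]][1L],
                      ignore.case = TRUE)
  p <- utils::read.delim(path, header = has_header,
                         col.names = c("chromosome", "position", "nA", "nC",
                                       "nG", "nT"),
                         stringsAsFactors = FALSE)
  cnt <- as.matrix(p[, c("nA", "nC", "nG", "nT")])
  if (any(cnt < 0)) stop("negative base count at row ",
                         which(rowSums(cnt < 0) > 0)[1L])
  p$coverage <- as.integer(rowSums(cnt))
  out <- p[p$coverage >= min_depth, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Sufficient statistics: per site, coverage n and the two largest base
# counts c1 >= c2.  Aggregated with multiplicities for fast likelihood.
profile_stats <- function(profiles) {
  cnt <- as.matrix(profiles[, c("nA", "nC", "nG", "nT")])
  # partial sorting network for the two largest of four counts
  a <- pmax(cnt[, 1L], cnt[, 2L]); b <- pmin(cnt[, 1L], cnt[, 2L])
  d1 <- pmax(cnt[, 3L], cnt[, 4L]); d2 <- pmin(cnt[, 3L], cnt[, 4L])
  c1 <- pmax(a, d1)
  c2 <- ifelse(a >= d1, pmax(d1, b), pmax(a, d2))
  dt <- data.table::data.table(n = as.integer(rowSums(cnt)),
                               c1 = as.integer(c1), c2 = as.integer(c2))
  dt[, .(w = .N), by = .(n, c1, c2)]
}

# Log composite likelihood at (theta, eps) over aggregated stats.
profile_loglik <- function(theta, eps, st) {
  h <- theta / (1 + theta)
  # hom: c1 true-base reads, n - c1 errors
  l_hom <- st$c1 * log1p(-eps) + (st$n - st$c1) * log(eps / 3)
  # het: top-two counts are allele reads, rest errors
  pa <- (1 - eps) / 2 + eps / 6
  l_het <- (st$c1 + st$c2) * log(pa) + (st$n - st$c1 - st$c2) * log(eps / 3)
  m <- pmax(l_hom, l_het)
  sum(st$w * (m + log((1 - h) * exp(l_hom - m) + h * exp(l_het - m))))
}

#' Maximum-likelihood population mutation rate from site profiles
#'
#' Jointly maximizes the composite likelihood over theta (= 4*Ne*mu per
#' site) and the per-base sequencing error rate by a coarse grid followed
#' by Nelder-Mead refinement on log scale, and reports a 95%
#' profile-likelihood interval for theta (delta log-L = 1.92, error rate
#' re-maximized at each theta).
#'
#' @param profiles Profile `data.frame` (see [load_profiles()]); at least
#'   ~1e4 sites are recommended for a stable joint fit.
#' @param theta_bounds,error_bounds Optimization bounds.
#' @return List of class `theta_estimate`: `theta`, `ci_low`, `ci_high`,
#'   `error_rate`, `sites_used`, `loglik`, `at_lower_bound`.
#' @export
estimate_theta_ml <- function(profiles, theta_bounds = c(1e-6, 0.5),
                              error_bounds = c(1e-6, 0.2)) {
  if (!nrow(profiles)) stop("no profiles supplied")
  st <- profile_stats(profiles)
  monomorphic <- all(st$c1 == st$n)
  ll <- function(par) {
    th <- exp(par[1L]); ep <- exp(par[2L])
    if (th < theta_bounds[1L] || th > theta_bounds[2L] ||
        ep < error_bounds[1L] || ep > error_bounds[2L]) return(-Inf)
    profile_loglik(th, ep, st)
  }
  th_grid <- exp(seq(log(theta_bounds[1L]), log(theta_bounds[2L]),
                     length.out = 25L))
  ep_grid <- exp(seq(log(error_bounds[1L]), log(error_bounds[2L]),
                     length.out = 15L))
  grid <- expand.grid(th = th_grid, ep = ep_grid)
  gv <- mapply(function(th, ep) profile_loglik(th, ep, st),
               grid$th, grid$ep)
  best <- which.max(gv)
  opt <- stats::optim(c(log(grid$th[best]), log(grid$ep[best])), ll,
                      method = "Nelder-Mead",
                      control = list(fnscale = -1, maxit = 500L,
                                     reltol = 1e-10))
  theta_hat <- exp(opt$par[1L])
  eps_hat <- exp(opt$par[2L])
  lmax <- opt$value
  if (monomorphic) {
    warning("all profiles monomorphic; theta estimate at lower bound")
    theta_hat <- theta_bounds[1L]
  }
  # profile-likelihood CI: re-maximize eps at each theta
  prof <- function(th) {
    o <- stats::optimize(function(lep) profile_loglik(th, exp(lep), st),
                         log(error_bounds), maximum = TRUE, tol = 1e-8)
    o$objective
  }
  target <- lmax - 1.92
  ci_bound <- function(lo_side) {
    ends <- if (lo_side) c(theta_bounds[1L], theta_hat)
            else c(theta_hat, theta_bounds[2L])
    f <- function(th) prof(th) - target
    fa <- f(ends[1L]); fb <- f(ends[2L])
    if (lo_side && fa >= 0) return(theta_bounds[1L])
    if (!lo_side && fb >= 0) return(theta_bounds[2L])
    stats::uniroot(f, ends, tol = theta_hat * 1e-4)$root
  }
  ci_low <- if (monomorphic) theta_bounds[1L] else ci_bound(TRUE)
  ci_high <- ci_bound(FALSE)
  structure(list(theta = theta_hat, ci_low = ci_low, ci_high = ci_high,
                 error_rate = eps_hat, sites_used = nrow(profiles),
                 loglik = lmax, at_lower_bound = monomorphic),
            class = "theta_estimate")
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat(sprintf(
    "<theta_estimate> theta = %.4g [%.4g, %.4g], error rate = %.4g (%d sites)\n",
    x$theta, x$ci_low, x$ci_high, x$error_rate, x$sites_used))
  invisible(x)
}

#' Mutation rate per site per generation from theta
#'
#' `mu = theta / (4 Ne)` for a diploid population.
#'
#' @param theta Population mutation rate (4*Ne*mu), per site.
#' @param ne Ancestral effective population size.
#' @return Substitutions per site per generation.
#' @export
mu_per_generation <- function(theta, ne) {
  if (!is.finite(ne) || ne <= 0) stop("ne must be positive")
  if (theta < 0) stop("theta must be non-negative")
  theta / (4 * ne)
}

#' Mutation rate per site per year
#'
#' @param mu_gen Substitutions per site per generation.
#' @param generation_time Generation time in years.
#' @return Substitutions per site per year.
#' @export
mu_per_year <- function(mu_gen, generation_time) {
  if (!is.finite(generation_time) || generation_time <= 0)
    stop("generation_time must be positive")
  if (mu_gen < 0) stop("mu_gen must be non-negative")
  mu_gen / generation_time
}

#' Global heterozygosity and per-window SNP track
#'
#' Global heterozygosity is the total number of heterozygous sites divided
#' by the total number of unmasked (effective) bases, as a percentage;
#' per-window counts give the heterozygous-SNPs-per-megabase track.
#'
#' @param het_sites `data.frame` with columns `chromosome`, `position`
#'   (0-based bp).
#' @param effective_bases Named numeric vector: chromosome -> unmasked
#'   base count (the denominator).
#' @param chromosome_lengths Named numeric vector of chromosome lengths
#'   for windowing; defaults to `effective_bases`.
#' @param window_size Window width in bp (default 1 Mb).
#' @return List: `global_pct` (percent), `n_het`, `effective_bases`,
#'   `track` (`chromosome`, `window_start`, `value`).
#' @export
heterozygosity_summary <- function(het_sites, effective_bases,
                                   chromosome_lengths = NULL,
                                   window_size = 1e6) {
  if (sum(effective_bases) <= 0) stop("zero effective bases")
  if (is.null(chromosome_lengths)) chromosome_lengths <- effective_bases
  unknown <- setdiff(unique(het_sites$chromosome),
                     names(chromosome_lengths))
  if (length(unknown)) stop("het site on unknown chromosome: ", unknown[1L])
  track <- do.call(rbind, lapply(names(chromosome_lengths), function(ch) {
    pos <- het_sites$position[het_sites$chromosome == ch]
    v <- windowed_counts(pos, chromosome_lengths[[ch]], window_size)
    data.frame(chromosome = ch,
               window_start = (seq_along(v) - 1) * window_size,
               value = v, stringsAsFactors = FALSE)
  }))
  list(global_pct = 100 * nrow(het_sites) / sum(effective_bases),
       n_het = nrow(het_sites), effective_bases = sum(effective_bases),
       track = track)
}
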