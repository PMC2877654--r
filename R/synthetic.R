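#' Specification of the synthetic trait table
#'
#' Describes the shape of the species x trait matrix the generator emulates:
#' groups of mutually exclusive binary character states (defaults mirror a
#' tadpole trait list with six oral-disc shapes, six jaw-sheath shapes, and a
#' single eye-position flag) plus continuous morphological measurements
#' (keratodont row count, papillae count, and three relative body-shape
#' measures).  Exclusive multi-state characters are dummy-expanded: within a
#' group of two or more columns each species carries exactly one 1.  A
#' single-column group is an ordinary presence/absence flag.
#'
#' Species are organised into ecomorphological guilds: clusters of
#' functionally similar species, the structure that gives real trait pools
#' their functional redundancy and makes the FD-richness curve saturate.
#' Binary states are inherited from the guild (with a small mutation
#' probability) and continuous traits scatter tightly around a guild centre;
#' the jitter wraps around the trait range, so each continuous trait remains
#' exactly uniform in its declared range marginally.  `n_guilds = n_species`
#' (or `guild_jitter` large) recovers an unstructured pool.
#'
#' @param group_sizes named integer vector; number of binary state columns per
#'   exclusive character group.
#' @param continuous_ranges named list of `c(min, max)` per continuous trait.
#' @param n_guilds number of ecomorph guilds in the regional pool (default 8).
#' @param state_mutation probability that a species' binary state deviates
#'   from its guild's state (default 0.12).
#' @param guild_jitter half-width of the continuous within-guild scatter, as
#'   a fraction of the trait range (default 0.08).
#' @return an object of class `trait_spec`.
#' @examples
#' trait_spec()                      # 13 binary + 5 continuous = 18 traits
#' trait_spec(group_sizes = c(shape = 4), continuous_ranges = list())
#' @export
trait_spec <- function(group_sizes = c(oral_disc = 6L, jaw_sheath = 6L,
                                       eye_position = 1L),
                       continuous_ranges = list(
                         keratodont_rows = c(0, 8),
                         papillae = c(0, 60),
                         rel_oral_disc_width = c(0.1, 1),
                         rel_tail_muscle_height = c(0.1, 0.6),
                         rel_tail_length = c(0.45, 0.8)),
                       n_guilds = 8L, state_mutation = 0.12,
                       guild_jitter = 0.08) {
  group_sizes <- stats::setNames(as.integer(group_sizes), names(group_sizes))
  if (length(group_sizes) && is.null(names(group_sizes))) {
    names(group_sizes) <- sprintf("group%d", seq_along(group_sizes))
  }
  if (any(group_sizes < 1L)) stop("group sizes must be >= 1", call. = FALSE)
  for (nm in names(continuous_ranges)) {
    r <- continuous_ranges[[nm]]
    if (length(r) != 2L || !(r[1] < r[2])) {
      stop(sprintf("continuous range for '%s' must satisfy min < max", nm),
           call. = FALSE)
    }
  }
  if (n_guilds < 1L) stop("'n_guilds' must be at least 1", call. = FALSE)
  if (state_mutation < 0 || state_mutation > 1) {
    stop("'state_mutation' must lie in [0, 1]", call. = FALSE)
  }
  if (guild_jitter < 0) stop("'guild_jitter' must be non-negative", call. = FALSE)
  structure(
    list(group_sizes = group_sizes, continuous_ranges = continuous_ranges,
         n_traits = sum(group_sizes) + length(continuous_ranges),
         n_guilds = as.integer(n_guilds), state_mutation = state_mutation,
         guild_jitter = guild_jitter),
    class = "trait_spec"
  )
}

#' @export
print.trait_spec <- function(x, ...) {
  cat(sprintf("Trait spec: %d traits (%d binary in %d groups, %d continuous)\n",
              x$n_traits, sum(x$group_sizes), length(x$group_sizes),
              length(x$continuous_ranges)))
  invisible(x)
}

#' Generate a synthetic regional trait matrix
#'
#' Draws one species per row, organised into the spec's ecomorph guilds
#' (balanced guild sizes).  Within each multi-column binary group a guild
#' carries one uniformly chosen active state; each species inherits it,
#' mutating to a uniform random state with probability `state_mutation`
#' (exactly one 1 per group always holds, reproducing the dummy-coded
#' structure of an exclusive character).  Single-column binary groups are
#' guild-level Bernoulli(1/2) flags with the same mutation rule.  Each
#' continuous trait takes a uniform guild centre plus a `guild_jitter`
#' wrap-around scatter, so species cluster by guild while every continuous
#' trait stays exactly uniform within its declared range marginally.
#'
#' @param spec a [trait_spec()].
#' @param n_species size of the regional pool (default 36).
#' @param seed integer seed; the generator is a pure function of
#'   `(spec, n_species, seed)`.
#' @return a [trait_matrix()].
#' @examples
#' tm <- generate_trait_matrix(seed = 1)
#' dim(tm)
#' @export
generate_trait_matrix <- function(spec = trait_spec(), n_species = 36L,
                                  seed = 1L) {
  if (!inherits(spec, "trait_spec")) stop("'spec' must be a trait_spec",
                                          call. = FALSE)
  if (n_species < 2L) stop("the species pool must contain at least 2 species",
                           call. = FALSE)
  with_seed(seed, {
    n_guilds <- min(spec$n_guilds, n_species)
    guild <- sort(rep_len(seq_len(n_guilds), n_species))
    cols <- list(); kinds <- character(); groups <- character()
    for (g in seq_along(spec$group_sizes)) {
      k <- spec$group_sizes[g]
      gname <- names(spec$group_sizes)[g]
      if (k >= 2L) {
        state <- sample.int(k, n_guilds, replace = TRUE)[guild]
        mut <- runif(n_species) < spec$state_mutation
        state[mut] <- sample.int(k, sum(mut), replace = TRUE)
        block <- matrix(0, n_species, k)
        block[cbind(seq_len(n_species), state)] <- 1
      } else {
        state <- rbinom(n_guilds, 1L, 0.5)[guild]
        mut <- runif(n_species) < spec$state_mutation
        state[mut] <- rbinom(sum(mut), 1L, 0.5)
        block <- matrix(state, n_species, 1L)
      }
      colnames(block) <- if (k >= 2L) sprintf("%s_state%d", gname, seq_len(k))
                         else gname
      cols[[length(cols) + 1L]] <- block
      kinds <- c(kinds, rep("binary", k))
      groups <- c(groups, rep(gname, k))
    }
    for (nm in names(spec$continuous_ranges)) {
      r <- spec$continuous_ranges[[nm]]
      centre <- runif(n_guilds, r[1], r[2])[guild]
      jit <- runif(n_species, -spec$guild_jitter, spec$guild_jitter) *
             (r[2] - r[1])
      x <- r[1] + (centre + jit - r[1]) %% (r[2] - r[1])
      block <- matrix(x, n_species, 1L, dimnames = list(NULL, nm))
      cols[[length(cols) + 1L]] <- block
      kinds <- c(kinds, "continuous")
      groups <- c(groups, NA_character_)
    }
    values <- do.call(cbind, cols)
    rownames(values) <- sprintf("sp%02d", seq_len(n_species))
    trait_matrix(values, kinds, groups)
  })
}

#' Community-assembly scenario
#'
#' Bundles the rule and parameters under which synthetic communities are
#' drawn from the regional pool.  `rule = "neutral"` samples species
#' uniformly without replacement.  `"filtering"` draws a random habitat
#' optimum per site and samples species with weight
#' `exp(-lambda_i * gower(species, optimum))`, pulling co-occurring species
#' towards the optimum (trait convergence); the site intensity `lambda_i`
#' ramps quadratically with site richness (see [generate_communities()]).  `"competition"` assembles
#' greedily, each new species weighted by `exp(strength * min Gower distance
#' to the species already present)` (limiting similarity, trait divergence).
#' `strength = 0` reduces every rule to neutral.
#'
#' @param rule `"neutral"`, `"filtering"`, or `"competition"`.
#' @param strength non-negative filtering/competition intensity; 0 = neutral.
#' @param richness_range inclusive integer range of per-site species richness
#'   (default 2-18, drawn uniformly).
#' @param n_sites number of stream sites (default 29).
#' @param pool_size regional pool size (default 36).
#' @param seed integer seed.
#' @return an object of class `assembly_scenario`.
#' @export
assembly_scenario <- function(rule = c("neutral", "filtering", "competition"),
                              strength = 0, richness_range = c(2L, 18L),
                              n_sites = 29L, pool_size = 36L, seed = 1L) {
  rule <- match.arg(rule)
  if (strength < 0) stop("'strength' must be non-negative", call. = FALSE)
  richness_range <- as.integer(richness_range)
  if (length(richness_range) != 2L || richness_range[1] > richness_range[2]) {
    stop("'richness_range' must be an inclusive integer interval", call. = FALSE)
  }
  if (richness_range[1] < 1L) stop("richness must be at least 1", call. = FALSE)
  if (richness_range[2] > pool_size) {
    stop("maximum richness exceeds the pool size", call. = FALSE)
  }
  structure(
    list(rule = rule, strength = strength, richness_range = richness_range,
         n_sites = as.integer(n_sites), pool_size = as.integer(pool_size),
         seed = as.integer(seed)),
    class = "assembly_scenario"
  )
}

#' Generate synthetic communities from a trait pool
#'
#' Site richness is drawn uniformly from the scenario's richness range and
#' then met exactly; membership is sampled according to the scenario rule
#' (see [assembly_scenario()]).
#'
#' Filtering intensity ramps with richness: the effective weight exponent of
#' site `i` is `strength * ((S_i - S_min) / (S_max - S_min))^2` over the
#' scenario's richness range, so species-poor sites assemble almost
#' neutrally while species-rich sites are strongly filtered --- the
#' richness-dependent environmental filtering characteristic of large-stream
#' communities.  The site optimum is the trait profile of a uniformly drawn
#' pool species (filters select towards viable ecomorphs).
#'
#' @param traits the regional [trait_matrix()]; its number of species must
#'   equal the scenario's `pool_size`.
#' @param scenario an [assembly_scenario()].
#' @return a site x species 0/1 matrix of class `community_table`.
#' @examples
#' tm <- generate_trait_matrix(seed = 1)
#' cm <- generate_communities(tm, assembly_scenario("neutral", seed = 2))
#' table(rowSums(cm))
#' @export
generate_communities <- function(traits, scenario) {
  if (!inherits(scenario, "assembly_scenario")) {
    stop("'scenario' must be an assembly_scenario", call. = FALSE)
  }
  N <- nrow(traits$values)
  if (N != scenario$pool_size) {
    stop(sprintf("trait pool has %d species but scenario expects %d",
                 N, scenario$pool_size), call. = FALSE)
  }
  D <- gower_distance(traits)
  sp <- species_labels(traits)
  with_seed(scenario$seed, {
    rng <- seq(scenario$richness_range[1], scenario$richness_range[2])
    S <- rng[sample.int(length(rng), scenario$n_sites, replace = TRUE)]
    P <- matrix(0L, scenario$n_sites, N,
                dimnames = list(sprintf("site%02d", seq_len(scenario$n_sites)),
                                sp))
    for (i in seq_len(scenario$n_sites)) {
      idx <- switch(scenario$rule,
        neutral = sample.int(N, S[i]),
        filtering = {
          rr <- scenario$richness_range
          ramp <- if (rr[2] > rr[1]) ((S[i] - rr[1]) / (rr[2] - rr[1]))^2
                  else 1
          opt <- traits$values[sample.int(N, 1L), ]
          w <- exp(-scenario$strength * ramp * gower_to_profile(traits, opt))
          sample.int(N, S[i], prob = w)
        },
        competition = {
          chosen <- sample.int(N, 1L)
          while (length(chosen) < S[i]) {
            rest <- setdiff(seq_len(N), chosen)
            mind <- apply(D[rest, chosen, drop = FALSE], 1, min)
            nxt <- rest[sample.int(length(rest), 1L,
                                   prob = exp(scenario$strength * mind))]
            chosen <- c(chosen, nxt)
          }
          chosen
        })
      P[i, idx] <- 1L
    }
    structure(P, class = c("community_table", class(P)))
  })
}

# Gower distance from every pool species to a single trait profile.
gower_to_profile <- function(traits, profile) {
  X <- traits$values
  contrib <- matrix(0, nrow(X), ncol(X))
  for (j in seq_len(ncol(X))) {
    if (traits$kinds[j] == "continuous") {
      rng <- traits$ranges["max", j] - traits$ranges["min", j]
      contrib[, j] <- abs(X[, j] - profile[j]) / rng
    } else {
      contrib[, j] <- as.numeric(X[, j] != profile[j])
    }
  }
  rowMeans(contrib)
}

#' Species richness of a community table
#' @param communities site x species presence matrix.
#' @return integer vector of per-site species counts.
#' @export
species_richness <- function(communities) {
  rowSums(community_matrix(communities))
}

#' Generate synthetic stream/forest habitat variables
#'
#' Emulates a 14-variable habitat table whose dominant structure is a single
#' latent stream size--velocity gradient: wide, slow, open-canopy streams
#' with abundant dragonfly larvae and coarse substrate at one end; narrow,
#' steep, densely shaded streams with fine substrate at the other.  The
#' latent axis is constructed to correlate with site species richness at
#' Pearson `r ~ coupling`.  Stream width and dragonfly counts load
#' positively on the axis; slope and both canopy covers load negatively;
#' the four microhabitat percentages (leaves, sand, gravel, rock) are a
#' softmax composition summing to 100 per site, with leaves/sand decreasing
#' and gravel/rock increasing along the axis.  Mayfly larvae, shrubs, trees,
#' leaf-litter depth, and riparian vegetation are independent noise.
#'
#' @param communities a community table (only per-site richness is used).
#' @param coupling target correlation in `[0, 1]` between the latent gradient
#'   and species richness.
#' @param seed integer seed.
#' @return a data.frame of class `habitat_table` with 14 named columns;
#'   the latent gradient is attached as attribute `"latent_axis"`.
#' @examples
#' tm <- generate_trait_matrix(seed = 1)
#' cm <- generate_communities(tm, assembly_scenario("neutral", seed = 2))
#' hb <- generate_habitat(cm, coupling = 0.8, seed = 3)
#' colnames(hb)
#' @export
generate_habitat <- function(communities, coupling = 0.8, seed = 1L) {
  if (coupling < 0 || coupling > 1) stop("'coupling' must lie in [0, 1]",
                                         call. = FALSE)
  SR <- species_richness(communities)
  n <- length(SR)
  with_seed(seed, {
    srz <- if (stats::sd(SR) > 0) (SR - mean(SR)) / stats::sd(SR) else rep(0, n)
    z <- coupling * srz + sqrt(1 - coupling^2) * rnorm(n)

    micro_lin <- cbind(leaves = 0.6 - 0.4 * z, sand = 0.4 - 0.4 * z,
                       gravel = 0.2 + 0.4 * z, rock = 0 + 0.4 * z) +
                 matrix(rnorm(4L * n, sd = 0.3), n, 4L)
    micro <- exp(micro_lin)
    micro <- 100 * micro / rowSums(micro)

    hb <- data.frame(
      width = exp(0.8 + 0.5 * z + 0.3 * rnorm(n)),
      slope = exp(0.3 - 0.5 * z + 0.3 * rnorm(n)),
      stream_canopy = stats::plogis(0.5 - 1.2 * z + 0.8 * rnorm(n)),
      leaves = micro[, "leaves"], sand = micro[, "sand"],
      gravel = micro[, "gravel"], rock = micro[, "rock"],
      dragonfly_larvae = stats::rpois(n, exp(1.2 + 0.6 * z)),
      mayfly_larvae = stats::rpois(n, 8),
      shrubs = stats::rpois(n, 12),
      trees = stats::rpois(n, 6),
      forest_canopy = 100 * stats::plogis(1.2 - 1.2 * z + 0.8 * rnorm(n)),
      leaf_litter = exp(0.5 + 0.4 * rnorm(n)),
      riparian_veg = stats::rpois(n, 15),
      row.names = rownames(community_matrix(communities))
    )
    attr(hb, "latent_axis") <- z
    class(hb) <- c("habitat_table", class(hb))
    hb
  })
}

#' Area coverage of the transect sampling design
#'
#' Perpendicular transects of fixed width laid at regular intervals across a
#' stream section sample a fraction `n * width / length` of its area.  With
#' the default design (ten 1-m transects over a 30-m section) coverage is
#' one third.
#'
#' @param n_transects number of transects.
#' @param transect_width transect width in metres.
#' @param section_length stream section length in metres.
#' @return percentage of the section area covered.
#' @examples
#' transect_coverage()  # 33.3%
#' @export
transect_coverage <- function(n_transects = 10, transect_width = 1,
                              section_length = 30) {
  if (n_transects * transect_width > section_length) {
    stop("transects exceed the section length", call. = FALSE)
  }
  100 * n_transects * transect_width / section_length
}
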