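#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles everything the forward Wright-Fisher simulator needs: genome
#' layout, mutation and recombination rates, the mixture of mutational
#' effect classes with their selection (`s`) and dominance (`h`)
#' coefficients and conservation-score distributions, and the demography.
#'
#' Selection convention: `s <= 0` is deleterious. Fitness is multiplicative
#' across sites with per-site factors `1`, `1 + h*s`, `1 + s` for 0, 1, 2
#' derived copies, and offspring survive with probability equal to their
#' fitness (viability selection).
#'
#' The simulator starts from standing variation rather than a monomorphic
#' population: `n_init_sites` segregating sites are seeded with derived
#' counts drawn from the neutral 1/i site-frequency spectrum, so that
#' desk-scale runs carry realistic diversity into the bottleneck.
#'
#' @param n_chromosomes number of independently assorting chromosomes.
#' @param chrom_length_bp length of each chromosome in bp.
#' @param mu per-bp per-generation mutation probability.
#' @param rec_rate per-bp per-generation crossover probability.
#' @param n_init_sites number of standing variants at generation zero.
#' @param class_probs named numeric, probability of each effect class
#'   (`neutral`, `low`, `moderate`, `high`); must sum to 1.
#' @param s_by_class,h_by_class named numeric, selection and dominance
#'   coefficient per class; `s` in `[-1, 0]` for deleterious classes.
#' @param gerp_ranges named list of length-2 numeric ranges; conservation
#'   scores are drawn uniformly within the class range. The `high` range
#'   must sit inside the configured top bin (default > 5.88).
#' @param demography list of stages from [epoch()], [bottleneck_to_pair()],
#'   [split_event()] and [sample_event()], executed in order.
#' @param genotype_error per-genotype probability of replacing the emitted
#'   dosage with a different one (crude caller-error model).
#' @param missing_rate per-genotype probability of emitting a missing call.
#' @param seed integer RNG seed used by [simulate_cohort()] by default.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 6,
                       chrom_length_bp = 2e6,
                       mu = 2.3e-9,
                       rec_rate = 1e-8,
                       n_init_sites = 10000,
                       class_probs = c(neutral = 0.90, low = 0.05,
                                       moderate = 0.035, high = 0.015),
                       s_by_class = c(neutral = 0, low = -0.002,
                                      moderate = -0.02, high = -0.2),
                       h_by_class = c(neutral = 0.5, low = 0.5,
                                      moderate = 0.3, high = 0.05),
                       gerp_ranges = list(neutral = c(-2, 1),
                                          low = c(1, 3),
                                          moderate = c(3, 5.88),
                                          high = c(5.88, 12)),
                       demography = default_demography(),
                       genotype_error = 0,
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- structure(
    list(n_chromosomes = as.integer(n_chromosomes),
         chrom_length_bp = as.numeric(chrom_length_bp),
         mu = mu, rec_rate = rec_rate,
         n_init_sites = as.integer(n_init_sites),
         class_probs = class_probs,
         s_by_class = s_by_class, h_by_class = h_by_class,
         gerp_ranges = gerp_ranges,
         demography = demography,
         genotype_error = genotype_error,
         missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config a `sim_config`.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cp <- config$class_probs
  if (abs(sum(cp) - 1) > 1e-9) {
    stop("class_probs must sum to 1 (got ", format(sum(cp)), ")")
  }
  if (any(cp < 0)) stop("class_probs must be non-negative")
  cls <- names(cp)
  if (!all(cls %in% names(config$s_by_class)) ||
      !all(cls %in% names(config$h_by_class)) ||
      !all(cls %in% names(config$gerp_ranges))) {
    stop("every class in class_probs needs s, h and a gerp range")
  }
  if (any(config$s_by_class > 0) || any(config$s_by_class < -1)) {
    stop("selection coefficients must lie in [-1, 0] (s <= 0 = deleterious)")
  }
  if (config$mu < 0 || config$rec_rate < 0) stop("mu and rec_rate must be >= 0")
  if (config$n_chromosomes < 1 || config$chrom_length_bp < 1) {
    stop("genome must have at least one chromosome of positive length")
  }
  for (st in config$demography) {
    if (!st$type %in% c("epoch", "split", "sample")) {
      stop("unknown demography stage type: ", st$type)
    }
    if (st$type == "epoch" && (st$size < 1 || st$n_gen < 0)) {
      stop("epoch sizes must be >= 1 and lengths >= 0")
    }
  }
  invisible(config)
}

#' Demography stages
#'
#' Stages are executed in order by [simulate_cohort()]. Populations are
#' referenced by name; the simulation starts with a single population
#' called `"source"`. Because populations exchange no migrants after a
#' split, sequential execution of their epochs is distributionally
#' equivalent to parallel evolution.
#'
#' @param pop population the stage applies to.
#' @param n_gen number of generations.
#' @param size diploid population size during (or, with `ramp = TRUE`, at
#'   the end of) the epoch.
#' @param ramp if `TRUE`, interpolate sizes geometrically from the current
#'   size to `size` over the epoch (recovery growth).
#' @return A stage list consumed by [simulate_cohort()].
#' @export
epoch <- function(pop, n_gen, size, ramp = FALSE) {
  list(type = "epoch", pop = pop, n_gen = as.integer(n_gen),
       size = as.integer(size), ramp = isTRUE(ramp))
}

#' @rdname epoch
#' @export
bottleneck_to_pair <- function(pop, n_gen = 1) {
  epoch(pop, n_gen, 2L)
}

#' @rdname epoch
#' @param from,to source population and name of the newly founded one.
#' @param n_moved number of individuals translocated to found `to`.
#' @export
split_event <- function(from, to, n_moved) {
  list(type = "split", from = from, to = to, n_moved = as.integer(n_moved))
}

#' @rdname epoch
#' @param label sample label recorded in the emitted callset.
#' @param n number of individuals sampled (copied, not removed).
#' @export
sample_event <- function(pop, label, n) {
  list(type = "sample", pop = pop, label = label, n = as.integer(n))
}

#' Default desk-scale demography template
#'
#' A stylised near-extinction narrative: a stable source population, a
#' crash, one generation as a single breeding pair, recovery, and a
#' translocation founding a second isolated population. Pre-crash
#' individuals are sampled as the "historical" cohort; both modern
#' populations are sampled at the end. The template mirrors the shape of
#' the history, not absolute census numbers.
#'
#' @return A list of demography stages.
#' @export
default_demography <- function() {
  list(
    epoch("source", 40, 500),
    sample_event("source", "historical", 13),
    epoch("source", 10, 50),
    bottleneck_to_pair("source", 1),
    epoch("source", 10, 60, ramp = TRUE),
    split_event("source", "translocated", 20),
    epoch("source", 15, 40),
    epoch("translocated", 15, 20),
    sample_event("source", "popA", 9),
    sample_event("translocated", "popB", 20)
  )
}

#' Draw mutational effects for new sites
#'
#' Samples an effect class from `class_probs` and, per class, the
#' configured selection and dominance coefficients plus a conservation
#' score drawn uniformly from the class's score range. High-class scores
#' therefore fall in the configured top bin.
#'
#' @param n number of sites to draw.
#' @param config a [sim_config()].
#' @return data.frame with columns `class`, `s`, `h`, `gerp`.
#' @export
draw_site_effect <- function(n, config) {
  validate_sim_config(config)
  cls <- names(config$class_probs)
  cl <- cls[sample.int(length(cls), n, replace = TRUE,
                       prob = config$class_probs)]
  rng <- config$gerp_ranges[cl]
  lo <- vapply(rng, `[`, numeric(1), 1L)
  hi <- vapply(rng, `[`, numeric(1), 2L)
  data.frame(class = cl,
             s = unname(config$s_by_class[cl]),
             h = unname(config$h_by_class[cl]),
             gerp = stats::runif(n, lo, hi))
}
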