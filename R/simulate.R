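#' Simulate a bottlenecked two-population cohort
#'
#' Forward diploid Wright-Fisher simulation with viability selection,
#' recombination, and mutation in effect classes. The demography in
#' `config` is executed stage by stage; individuals sampled by
#' [sample_event()] stages are emitted into the returned callset, and all
#' sites segregating among the emitted individuals become callset sites
#' (sites fixed derived across every emitted genome are dropped and
#' counted).
#'
#' Life cycle per generation: offspring are formed from two distinct,
#' uniformly chosen parents; each gamete picks a starting haplotype per
#' chromosome (independent assortment) and recombines at Poisson-distributed
#' crossover points; offspring survive with probability equal to their
#' relative fitness (multiplicative fitness scaled by the fittest candidate,
#' i.e. soft viability selection, so a loaded population is selected within
#' rather than demographically starved); new mutations are then placed on
#' the survivors' gametes at infinite-sites positions (collisions redrawn).
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`. Identical
#'   (config, seed) pairs give byte-identical outputs.
#' @return A list of class `sim_cohort` with elements
#'   \describe{
#'     \item{callset}{a polarized [cohort_callset()] (derived dosages).}
#'     \item{annotation}{site annotation data.frame (`chrom`, `pos`,
#'       `gerp`, `impact`) with impact `MODIFIER`/`LOW`/`MODERATE`/`HIGH`.}
#'     \item{truth}{ground truth: `sites` (effect class, s, h, gerp per
#'       callset site) and `individuals` (sample, population, generation,
#'       realized homozygosity fraction).}
#'     \item{n_fixed_dropped}{sites fixed derived in all emitted genomes.}
#'   }
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  n_chrom <- config$n_chromosomes
  L <- config$chrom_length_bp
  mu <- config$mu

  # --- site registry (grows, never pruned; ids are row indices) ----------
  reg <- list(chrom = integer(0), pos = integer(0), class = character(0),
              s = numeric(0), h = numeric(0), gerp = numeric(0))
  reg_key <- numeric(0)  # (chrom-1)*L + pos, for collision checks

  new_sites <- function(n) {
    # draw n unique never-used positions and their effects
    chrom <- sample.int(n_chrom, n, replace = TRUE)
    pos <- sample.int(L, n, replace = TRUE)
    k <- (chrom - 1) * L + pos
    bad <- which(duplicated(k) | k %in% reg_key)
    while (length(bad)) {
      chrom[bad] <- sample.int(n_chrom, length(bad), replace = TRUE)
      pos[bad] <- sample.int(L, length(bad), replace = TRUE)
      k <- (chrom - 1) * L + pos
      bad <- which(duplicated(k) | k %in% reg_key)
    }
    eff <- draw_site_effect(n, config)
    ids <- length(reg$chrom) + seq_len(n)
    reg$chrom <<- c(reg$chrom, chrom)
    reg$pos <<- c(reg$pos, pos)
    reg$class <<- c(reg$class, eff$class)
    reg$s <<- c(reg$s, eff$s)
    reg$h <<- c(reg$h, eff$h)
    reg$gerp <<- c(reg$gerp, eff$gerp)
    reg_key <<- c(reg_key, k)
    ids
  }

  # --- active state -------------------------------------------------------
  # act_ids: registry ids of active rows; pops: logical matrices (row=site,
  # col=haplotype) sharing the same row order across populations.
  act_ids <- integer(0)
  pops <- list()
  pop_gen <- numeric(0)
  emitted <- list()

  active_chrom_rows <- function() {
    split(seq_along(act_ids), factor(reg$chrom[act_ids], levels = seq_len(n_chrom)))
  }

  make_offspring <- function(H, n_off, rows_by_chrom, pos_act) {
    N <- ncol(H) %/% 2L
    p1 <- sample.int(N, n_off, replace = TRUE)
    p2 <- sample.int(N, n_off, replace = TRUE)
    clash <- which(p1 == p2)
    while (length(clash)) {
      p2[clash] <- sample.int(N, length(clash), replace = TRUE)
      clash <- clash[p1[clash] == p2[clash]]
    }
    n_gam <- 2L * n_off
    parent <- integer(n_gam)
    parent[seq(1L, n_gam, 2L)] <- p1
    parent[seq(2L, n_gam, 2L)] <- p2
    Hoff <- matrix(as.raw(0), nrow(H), n_gam)
    for (cc in seq_len(n_chrom)) {
      rows <- rows_by_chrom[[cc]]
      if (!length(rows)) next
      base <- 2L * parent - stats::rbinom(n_gam, 1L, 0.5)
      Hoff[rows, ] <- H[rows, base]
      k <- stats::rpois(n_gam, config$rec_rate * L)
      for (g in which(k > 0L)) {
        bp <- sort(stats::runif(k[g], 0, L))
        swap <- findInterval(pos_act[rows], bp) %% 2L == 1L
        if (any(swap)) {
          other <- base[g] + if (base[g] %% 2L == 0L) -1L else 1L
          Hoff[rows[swap], g] <- H[rows[swap], other]
        }
      }
    }
    Hoff
  }

  viability <- function(Hoff, sel_rows, s_sel, h_sel) {
    n_off <- ncol(Hoff) %/% 2L
    if (!length(sel_rows)) return(rep(1, n_off))
    odd <- seq(1L, ncol(Hoff), 2L)
    a1 <- Hoff[sel_rows, odd, drop = FALSE]
    D <- matrix(as.integer(a1), nrow(a1)) +
      matrix(as.integer(Hoff[sel_rows, odd + 1L, drop = FALSE]), nrow(a1))
    fac <- 1 + (D == 1L) * (h_sel * s_sel) + (D == 2L) * s_sel
    w <- exp(colSums(log(fac)))
    w[is.nan(w)] <- 0
    pmin(pmax(w, 0), 1)
  }

  advance <- function(pop, N_next) {
    H <- pops[[pop]]
    N <- ncol(H) %/% 2L
    gen <- pop_gen[[pop]] + 1
    if (N < 2L) {
      stop(sprintf("population '%s' cannot reproduce at generation %d (size %d < 2)",
                   pop, gen, N))
    }
    sel_rows <- which(reg$s[act_ids] != 0)
    s_sel <- reg$s[act_ids][sel_rows]
    h_sel <- reg$h[act_ids][sel_rows]
    rows_by_chrom <- active_chrom_rows()
    pos_act <- reg$pos[act_ids]
    kept <- list()
    n_surv <- 0L
    tries <- 0L
    acc <- 1  # running estimate of the batch acceptance rate
    while (n_surv < N_next) {
      tries <- tries + 1L
      if (tries > 60L) {
        stop(sprintf("population '%s' went extinct at generation %d (no viable offspring)",
                     pop, gen))
      }
      n_off <- max(ceiling((N_next - n_surv) / acc), 4L)
      Hoff <- make_offspring(H, n_off, rows_by_chrom, pos_act)
      w <- viability(Hoff, sel_rows, s_sel, h_sel)
      wmax <- max(w)
      if (wmax == 0) {
        stop(sprintf("population '%s' went extinct at generation %d (all offspring fitness 0)",
                     pop, gen))
      }
      keep <- which(stats::runif(n_off) < w / wmax)
      acc <- max(0.1, min(1, (length(keep) + 1) / (n_off + 1)))
      if (length(keep)) {
        cols <- as.vector(rbind(2L * keep - 1L, 2L * keep))
        kept[[length(kept) + 1L]] <- Hoff[, cols, drop = FALSE]
        n_surv <- n_surv + length(keep)
      }
    }
    Hn <- do.call(cbind, kept)[, seq_len(2L * N_next), drop = FALSE]
    # mutation on the survivors' gametes
    n_new <- stats::rpois(1, 2 * N_next * n_chrom * L * mu)
    if (n_new > 0L) {
      ids <- new_sites(n_new)
      carrier <- sample.int(2L * N_next, n_new, replace = TRUE)
      M <- matrix(as.raw(0), n_new, 2L * N_next)
      M[cbind(seq_len(n_new), carrier)] <- as.raw(1)
      Hn <- rbind(Hn, M)
      for (q in setdiff(names(pops), pop)) {
        pops[[q]] <<- rbind(pops[[q]], matrix(as.raw(0), n_new, ncol(pops[[q]])))
      }
      act_ids <<- c(act_ids, ids)
    }
    pops[[pop]] <<- Hn
    pop_gen[[pop]] <<- gen
    # prune sites lost from every current population (emitted copies are
    # stored by id and unaffected)
    carriers <- Reduce(`+`, lapply(pops, function(m) rowSums(m != as.raw(0))))
    dead <- carriers == 0
    if (length(dead) && mean(dead) > 0.05) {
      act_ids <<- act_ids[!dead]
      for (q in names(pops)) pops[[q]] <<- pops[[q]][!dead, , drop = FALSE]
    }
    invisible(NULL)
  }

  # --- initial population -------------------------------------------------
  stages <- config$demography
  first <- stages[[1L]]
  if (first$type != "epoch") stop("demography must start with an epoch")
  N0 <- first$size
  if (config$n_init_sites > 0L && N0 >= 1L) {
    ids <- new_sites(config$n_init_sites)
    n0 <- length(ids)
    hap_n <- 2L * N0
    cnt <- if (hap_n > 2L) {
      sample.int(hap_n - 1L, n0, replace = TRUE, prob = 1 / seq_len(hap_n - 1L))
    } else rep(1L, n0)
    H0 <- matrix(as.raw(0), n0, hap_n)
    rows <- rep(seq_len(n0), cnt)
    cols <- unlist(lapply(cnt, function(k) sample.int(hap_n, k)))
    H0[cbind(rows, cols)] <- as.raw(1)
    pops[[first$pop]] <- H0
    act_ids <- ids
  } else {
    pops[[first$pop]] <- matrix(as.raw(0), 0L, 2L * N0)
  }
  pop_gen[[first$pop]] <- 0

  # --- run the demography -------------------------------------------------
  for (st in stages) {
    if (st$type == "epoch") {
      if (is.null(pops[[st$pop]])) stop("epoch references unknown population: ", st$pop)
      cur <- ncol(pops[[st$pop]]) %/% 2L
      sizes <- if (st$ramp && st$n_gen > 0L) {
        round(exp(seq(log(cur), log(st$size), length.out = st$n_gen + 1L)))[-1L]
      } else rep(st$size, st$n_gen)
      for (Ng in sizes) advance(st$pop, as.integer(Ng))
    } else if (st$type == "split") {
      if (is.null(pops[[st$from]])) stop("split references unknown population: ", st$from)
      N <- ncol(pops[[st$from]]) %/% 2L
      if (st$n_moved >= N) stop("split would empty population '", st$from, "'")
      idx <- sample.int(N, st$n_moved)
      cols <- as.vector(rbind(2L * idx - 1L, 2L * idx))
      pops[[st$to]] <- pops[[st$from]][, cols, drop = FALSE]
      pops[[st$from]] <- pops[[st$from]][, -cols, drop = FALSE]
      pop_gen[[st$to]] <- pop_gen[[st$from]]
    } else if (st$type == "sample") {
      if (is.null(pops[[st$pop]])) stop("sample references unknown population: ", st$pop)
      H <- pops[[st$pop]]
      N <- ncol(H) %/% 2L
      if (st$n > N) stop(sprintf("cannot sample %d of %d individuals from '%s'",
                                 st$n, N, st$pop))
      idx <- sort(sample.int(N, st$n))
      for (i in idx) {
        emitted[[length(emitted) + 1L]] <- list(
          label = st$label, pop = st$pop, generation = pop_gen[[st$pop]],
          hap1 = act_ids[H[, 2L * i - 1L] != as.raw(0)],
          hap2 = act_ids[H[, 2L * i] != as.raw(0)])
      }
    }
  }
  if (!length(emitted)) stop("demography emitted no samples")

  # --- assemble the callset ----------------------------------------------
  ids_used <- sort(unique(unlist(lapply(emitted, function(e) c(e$hap1, e$hap2)))))
  S <- length(ids_used)
  nsamp <- length(emitted)
  D <- matrix(0L, S, nsamp)
  for (j in seq_len(nsamp)) {
    D[, j] <- tabulate(match(emitted[[j]]$hap1, ids_used), nbins = S) +
      tabulate(match(emitted[[j]]$hap2, ids_used), nbins = S)
  }
  fixed <- rowSums(D) == 2L * nsamp
  n_fixed_dropped <- sum(fixed)
  ids_used <- ids_used[!fixed]
  D <- D[!fixed, , drop = FALSE]
  S <- length(ids_used)

  ord <- order(reg$chrom[ids_used], reg$pos[ids_used])
  ids_used <- ids_used[ord]
  D <- D[ord, , drop = FALSE]

  # per-genotype noise (off by default)
  if (config$genotype_error > 0 && S > 0L) {
    hit <- which(stats::runif(length(D)) < config$genotype_error)
    D[hit] <- (D[hit] + sample(1:2, length(hit), replace = TRUE)) %% 3L
  }
  if (config$missing_rate > 0 && S > 0L) {
    D[stats::runif(length(D)) < config$missing_rate] <- NA_integer_
  }

  labels <- vapply(emitted, `[[`, character(1), "label")
  within_label <- as.integer(stats::ave(seq_along(labels), labels, FUN = seq_along))
  samples <- sprintf("%s_%02d", labels, within_label)
  gens <- vapply(emitted, `[[`, numeric(1), "generation")

  bases <- c("A", "C", "G", "T")
  anc <- bases[sample.int(4L, S, replace = TRUE)]
  der <- bases[(match(anc, bases) - 1L + sample.int(3L, S, replace = TRUE)) %% 4L + 1L]

  sites <- data.frame(
    chrom = sprintf("chr%d", reg$chrom[ids_used]),
    pos = reg$pos[ids_used],
    ref = anc, alt = der, anc = anc, der = der,
    stringsAsFactors = FALSE)
  callset <- cohort_callset(
    sites = sites, G = D, samples = samples, populations = labels,
    callable_bp = rep(n_chrom * L, nsamp), polarized = TRUE)

  impact_map <- c(neutral = "MODIFIER", low = "LOW",
                  moderate = "MODERATE", high = "HIGH")
  cls <- reg$class[ids_used]
  annotation <- data.frame(
    chrom = sites$chrom, pos = sites$pos,
    gerp = reg$gerp[ids_used],
    impact = unname(impact_map[cls]),
    stringsAsFactors = FALSE)

  truth <- list(
    sites = data.frame(chrom = sites$chrom, pos = sites$pos, class = cls,
                       s = reg$s[ids_used], h = reg$h[ids_used],
                       gerp = reg$gerp[ids_used], stringsAsFactors = FALSE),
    individuals = data.frame(sample = samples, population = labels,
                             generation = gens,
                             hom_fraction = if (S > 0L) colMeans(D != 1L, na.rm = TRUE)
                                            else rep(NA_real_, nsamp),
                             stringsAsFactors = FALSE))

  structure(list(callset = callset, annotation = annotation, truth = truth,
                 n_fixed_dropped = n_fixed_dropped, config = config,
                 seed = seed),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort (seed %d): %d sites x %d samples; %d fixed sites dropped\n",
              x$seed, nrow(x$callset$sites), length(x$callset$samples),
              x$n_fixed_dropped))
  print(x$callset)
  invisible(x)
}
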