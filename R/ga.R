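#' Gray code conversions
#'
#' Reflected binary (Gray) coding for the overlap gene: consecutive integers
#' differ in exactly one bit, so a single-bit mutation moves the decoded
#' overlap by at most one step most of the time.
#'
#' @param k non-negative integer.
#' @param width number of bits.
#' @return `gray_encode` returns an integer 0/1 vector (most significant bit
#'   first); `gray_decode` returns the integer a bit vector encodes.
#' @export
gray_encode <- function(k, width) {
  g <- bitwXor(k, bitwShiftR(k, 1L))
  as.integer(intToBits(g)[width:1])
}

#' @rdname gray_encode
#' @param bits integer 0/1 vector, most significant bit first.
#' @export
gray_decode <- function(bits) {
  b <- cumsum(bits) %% 2L  # prefix XOR undoes the Gray reflection
  sum(b * 2L^((length(bits) - 1L):0L))
}

OVERLAP_BITS <- 7L
OVERLAP_LEVELS <- 81L  # integer percents 10..90

# 7-bit Gray codes rescale onto the 81 integer-percent levels; rounding the
# rescaled value keeps the map onto [10, 90] near-uniform (a modulo wrap
# would double-cover the lower half of the range and bias a random search
# toward low overlaps).
code_to_level <- function(code) as.integer(round(code * (OVERLAP_LEVELS - 1L) / 127))
level_to_code <- function(level) as.integer(round(level * 127 / (OVERLAP_LEVELS - 1L)))

#' Chromosome layout
#'
#' Bit layout of an individual: a 7-bit Gray-coded overlap gene, then one
#' activation bit per channel, then `m` feature bits per channel
#' (`7 + n + n * m` bits; 2015 at the 8-channel, 250-sample defaults).
#'
#' @param n_channels number of EEG channels (default 8).
#' @param m candidate sample points per channel, equal to the window size
#'   (default 250).
#' @return A list with `n_channels`, `m`, `overlap_bits`, and total `length`.
#' @export
chromosome_layout <- function(n_channels = 8L, m = 250L) {
  list(n_channels = as.integer(n_channels), m = as.integer(m),
       overlap_bits = OVERLAP_BITS,
       length = OVERLAP_BITS + n_channels + n_channels * m)
}

#' Decode a chromosome into its phenotype
#'
#' The chromosome concatenates a 7-bit Gray-coded overlap gene, one
#' activation bit per channel, and `m` feature bits per channel. The overlap
#' gene decodes as `0.10 + round(gray / 127 * 80) / 100`, i.e. the Gray
#' integer rescaled onto the 81 integer-percent levels of `[0.10, 0.90]`. A
#' feature is active iff its own bit and its channel's bit are both 1.
#'
#' @param bits integer 0/1 vector of length `layout$length`.
#' @param layout a `chromosome_layout()` (7 + n + n*m bits).
#' @return A list of class `phenotype`: `overlap` (fraction), `overlap_pct`,
#'   `active_channels` (indices), `feature_mask` (n x m logical, channel
#'   gating applied), `per_channel` (selected count per channel), and
#'   `total_selected`.
#' @export
decode_chromosome <- function(bits, layout = chromosome_layout()) {
  if (length(bits) != layout$length)
    stop("chromosome has ", length(bits), " bits; layout expects ",
         layout$length)
  w <- layout$overlap_bits
  level <- code_to_level(gray_decode(bits[seq_len(w)]))
  overlap_pct <- 10L + level
  ch_bits <- bits[w + seq_len(layout$n_channels)]
  fmat <- matrix(bits[(w + layout$n_channels + 1L):layout$length],
                 nrow = layout$n_channels, ncol = layout$m, byrow = TRUE)
  mask <- (fmat == 1L) & (ch_bits == 1L)
  per_channel <- rowSums(mask)
  structure(list(overlap = overlap_pct / 100, overlap_pct = overlap_pct,
                 active_channels = which(ch_bits == 1L),
                 feature_mask = mask, per_channel = per_channel,
                 total_selected = sum(per_channel)),
            class = "phenotype")
}

#' @export
print.phenotype <- function(x, ...) {
  cat(sprintf("phenotype: overlap %d%%, %d active channel(s), %d selected feature(s)\n",
              x$overlap_pct, length(x$active_channels), x$total_selected))
  invisible(x)
}

#' Encode a phenotype back into chromosome bits
#'
#' Inverse of [decode_chromosome()] on canonical chromosomes (overlap codes
#' within the 81 levels; feature bits outside active channels set to the raw
#' feature mask given).
#'
#' @param overlap_pct integer percent in 10..90.
#' @param channel_bits integer 0/1 vector of channel activations.
#' @param feature_bits n x m 0/1 matrix of raw feature bits.
#' @param layout a `chromosome_layout()`.
#' @return Integer 0/1 chromosome vector.
#' @export
encode_chromosome <- function(overlap_pct, channel_bits, feature_bits,
                              layout = chromosome_layout()) {
  stopifnot(overlap_pct >= 10, overlap_pct <= 90)
  c(gray_encode(level_to_code(as.integer(overlap_pct) - 10L),
                layout$overlap_bits),
    as.integer(channel_bits), as.integer(t(feature_bits)))
}

random_chromosome <- function(layout, overlap_level = NULL) {
  bits <- sample(0:1, layout$length, replace = TRUE)
  if (!is.null(overlap_level))
    bits[seq_len(layout$overlap_bits)] <-
      gray_encode(level_to_code(as.integer(overlap_level)),
                  layout$overlap_bits)
  bits
}

# Stratified initial overlap levels: the overlap gene spans a 1-D range that
# uniform bits cover only sparsely at small population sizes, so the initial
# population is spread evenly over [10, 90]% while channel and feature bits
# stay uniform random.
init_overlap_levels <- function(pop_size) {
  as.integer(round(seq(0L, OVERLAP_LEVELS - 1L, length.out = pop_size)))
}

# Flatten an n x m channel/offset mask to column indices of the channel-major
# window matrix produced by extract_windows().
mask_to_columns <- function(mask) which(as.vector(t(mask)))

#' GA configuration
#'
#' @param pop_size population size (default 50).
#' @param generations number of generations (default 200).
#' @param crossover_rate probability a parent pair is recombined
#'   (default 0.9).
#' @param mutation_i,mutation_f initial and final per-bit flip probabilities
#'   of the linearly decaying uniform mutation; defaults `10 / eta` and
#'   `1 / eta` with `eta` the chromosome bit length.
#' @param eta scale of the mutation schedule; defaults to the chromosome
#'   length at decode time.
#' @param seed run seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 50, generations = 200, crossover_rate = 0.9,
                      mutation_i = NULL, mutation_f = NULL, eta = NULL,
                      seed = 1) {
  if (pop_size < 2) stop("`pop_size` must be >= 2")
  if (crossover_rate < 0 || crossover_rate > 1)
    stop("`crossover_rate` must lie in [0, 1]")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_i = mutation_i, mutation_f = mutation_f, eta = eta,
                 seed = as.integer(seed)),
            class = "ga_config")
}

mutation_prob <- function(g, cfg, eta) {
  mi <- if (is.null(cfg$mutation_i)) 10 / eta else cfg$mutation_i
  mf <- if (is.null(cfg$mutation_f)) 1 / eta else cfg$mutation_f
  if (mi < mf) stop("initial mutation probability must be >= final")
  G <- cfg$generations
  if (G <= 1L) return(mi)
  mi + (mf - mi) * g / (G - 1)
}

#' Binary tournament selection
#'
#' Draws two individuals uniformly with replacement and returns the fitter;
#' ties break toward fewer selected features, then toward the first drawn.
#'
#' @param pop list of evaluated individuals (each with `fitness` and
#'   `total_selected`).
#' @return The index of the winner in `pop`.
#' @export
tournament_select <- function(pop) {
  if (!length(pop)) stop("empty population")
  i <- sample.int(length(pop), 2L, replace = TRUE)
  a <- pop[[i[1L]]]; b <- pop[[i[2L]]]
  if (b$fitness > a$fitness ||
      (b$fitness == a$fitness && b$total_selected < a$total_selected))
    i[2L] else i[1L]
}

#' Uniform crossover
#'
#' With probability `rate`, every bit position independently swaps between
#' the two offspring with probability 0.5; otherwise the offspring are exact
#' copies of the parents. The per-position allele multiset is always
#' conserved.
#'
#' @param a,b parent chromosomes (equal-length 0/1 vectors).
#' @param rate crossover probability.
#' @return A list of two offspring chromosomes.
#' @export
uniform_crossover <- function(a, b, rate = 0.9) {
  if (length(a) != length(b)) stop("parent chromosomes differ in length")
  if (stats::runif(1) < rate) {
    swap <- stats::runif(length(a)) < 0.5
    tmp <- a[swap]
    a[swap] <- b[swap]
    b[swap] <- tmp
  }
  list(a, b)
}

#' Linearly decaying uniform mutation
#'
#' Flips each bit independently with probability
#' `M(g) = M_i + (M_f - M_i) * g / (G - 1)`, decaying from `M_i = 10 / eta`
#' at the first generation to `M_f = 1 / eta` at the last.
#'
#' @param bits chromosome.
#' @param g 0-based generation index.
#' @param cfg a [ga_config()].
#' @param eta mutation scale (chromosome length by default).
#' @return The mutated chromosome.
#' @export
mutate <- function(bits, g, cfg, eta = length(bits)) {
  p <- mutation_prob(g, cfg, eta)
  flip <- stats::runif(length(bits)) < p
  bits[flip] <- 1L - bits[flip]
  bits
}

#' mu+lambda survivor selection
#'
#' Pools parents and offspring and keeps the best `mu` by fitness, ties
#' broken toward fewer selected features. Because parents compete with their
#' offspring, the best fitness in the population never decreases.
#'
#' @param parents,offspring lists of evaluated individuals.
#' @param mu number of survivors.
#' @return A list of `mu` individuals.
#' @export
mu_plus_lambda <- function(parents, offspring, mu) {
  if (mu < 1) stop("`mu` must be >= 1")
  pool <- c(parents, offspring)
  if (mu > length(pool)) stop("`mu` exceeds pooled population size")
  fit <- vapply(pool, `[[`, 0, "fitness")
  tot <- vapply(pool, `[[`, 0, "total_selected")
  pool[order(-fit, tot)][seq_len(mu)]
}

# Per-overlap dataset cache: segmentation depends only on the decoded overlap,
# so train/validation window matrices are built once per overlap level.
dataset_cache <- function(train_rec, val_rec, size, max_entries = 40L) {
  env <- new.env(parent = emptyenv())
  env$keys <- character()
  function(overlap_pct) {
    key <- as.character(overlap_pct)
    if (!is.null(env[[key]])) return(env[[key]])
    overlap <- overlap_pct / 100
    val <- list(
      train = suppressWarnings(make_training_set(train_rec, size, overlap)),
      validation = make_sliding_set(val_rec, size, overlap, "validation"))
    if (length(env$keys) >= max_entries) {
      rm(list = env$keys[1L], envir = env)
      env$keys <- env$keys[-1L]
    }
    env[[key]] <- val
    env$keys <- c(env$keys, key)
    val
  }
}

chromosome_hash <- function(bits) {
  p <- 2147483629
  pow <- numeric(length(bits))
  pow[1L] <- 1
  for (i in seq_len(length(bits) - 1L)) pow[i + 1L] <- (pow[i] * 2) %% p
  sum(bits * pow) %% p
}

#' Wrapper fitness of a chromosome
#'
#' Decodes the chromosome, regenerates the training set (event-centred
#' windows at the decoded overlap) and the sliding validation set, sizes the
#' classifier from the number of selected features, trains it for the
#' configured epochs, and returns the validation F1. Phenotypes with no
#' active feature score 0 without training. Results are cached by genotype,
#' and the classifier seed is derived from the run seed and the genotype, so
#' re-evaluation is deterministic.
#'
#' @param bits chromosome.
#' @param ctx evaluation context from [fitness_context()].
#' @return Validation F1 in `[0, 1]`.
#' @export
ga_fitness <- function(bits, ctx) {
  key <- paste(bits, collapse = "")
  cached <- ctx$cache[[key]]
  if (!is.null(cached)) return(cached)

  phen <- decode_chromosome(bits, ctx$layout)
  f1 <- if (phen$total_selected == 0L) 0 else {
    ds <- ctx$datasets(phen$overlap_pct)
    cols <- mask_to_columns(phen$feature_mask)
    seed <- (ctx$seed * 7919 + chromosome_hash(bits)) %% 2147483629
    spec <- mlp_spec(IL = length(cols), epochs = ctx$epochs,
                     learning_rate = ctx$learning_rate,
                     batch_size = ctx$batch_size, threshold = ctx$threshold,
                     seed = seed, sizing_rule = ctx$sizing_rule)
    model <- suppressWarnings(
      mlp_train(ds$train$X[, cols, drop = FALSE], ds$train$label, spec))
    pred <- predict(model, ds$validation$X[, cols, drop = FALSE])
    score_windows(ds$validation, pred, ctx$scoring)$F1
  }
  ctx$cache[[key]] <- f1
  f1
}

#' Build a fitness-evaluation context
#'
#' Binds the preprocessed training/validation recordings and the classifier
#' hyper-parameters into the context [ga_fitness()] evaluates against.
#'
#' @param train_rec,val_rec preprocessed [eeg_recording()]s (the 70/30 split
#'   of the session recording).
#' @param layout a `chromosome_layout()`; the window size equals `layout$m`.
#' @param epochs,learning_rate,batch_size,threshold,sizing_rule classifier
#'   settings, see [mlp_spec()].
#' @param scoring validation scoring mode for [score_windows()] (default
#'   `"event"`).
#' @param seed run seed used to derive per-genotype classifier seeds.
#' @return An environment of class `fitness_context`.
#' @export
fitness_context <- function(train_rec, val_rec, layout = chromosome_layout(),
                            epochs = 10, learning_rate = 0.1,
                            batch_size = 32, threshold = 0.5,
                            sizing_rule = "cube_root", scoring = "event",
                            seed = 1) {
  ctx <- new.env(parent = emptyenv())
  ctx$layout <- layout
  ctx$datasets <- dataset_cache(train_rec, val_rec, layout$m)
  ctx$cache <- new.env(parent = emptyenv())
  ctx$epochs <- epochs
  ctx$learning_rate <- learning_rate
  ctx$batch_size <- batch_size
  ctx$threshold <- threshold
  ctx$sizing_rule <- sizing_rule
  ctx$scoring <- scoring
  ctx$seed <- seed
  class(ctx) <- "fitness_context"
  ctx
}

evaluate_individual <- function(bits, ctx) {
  phen <- decode_chromosome(bits, ctx$layout)
  list(bits = bits, fitness = ga_fitness(bits, ctx),
       total_selected = phen$total_selected)
}

#' Run the genetic algorithm
#'
#' Evolves a population of mixed Gray/binary chromosomes for
#' `cfg$generations` generations: binary tournament parent selection,
#' uniform crossover, linearly decaying uniform mutation, and mu+lambda
#' survivor selection with `mu = lambda = pop_size`. Fitness is the wrapper
#' validation F1 of [ga_fitness()]. Fully reproducible from `cfg$seed`.
#'
#' @param train_rec,val_rec preprocessed recordings (see
#'   [fitness_context()]).
#' @param cfg a [ga_config()].
#' @param layout a `chromosome_layout()`.
#' @param ... classifier settings passed to [fitness_context()].
#' @return A list of class `ga_result`: `best` (evaluated individual),
#'   `best_phenotype`, `log` (per-generation data frame with `generation`,
#'   `best_f1`, `mean_f1`), `population`, `cfg`, `layout`, and `n_evals`.
#' @export
ga_run <- function(train_rec, val_rec, cfg = ga_config(),
                   layout = chromosome_layout(), ...) {
  ctx <- fitness_context(train_rec, val_rec, layout, seed = cfg$seed, ...)
  eta <- if (is.null(cfg$eta)) layout$length else cfg$eta
  with_seed(cfg$seed, {
    levels0 <- init_overlap_levels(cfg$pop_size)
    pop <- lapply(seq_len(cfg$pop_size), function(i)
      evaluate_individual(random_chromosome(layout, levels0[i]), ctx))
    n_evals <- cfg$pop_size
    log <- data.frame(generation = integer(), best_f1 = numeric(),
                      mean_f1 = numeric())
    for (g in seq_len(cfg$generations) - 1L) {
      offspring <- vector("list", cfg$pop_size)
      k <- 1L
      while (k <= cfg$pop_size) {
        p1 <- pop[[tournament_select(pop)]]$bits
        p2 <- pop[[tournament_select(pop)]]$bits
        kids <- uniform_crossover(p1, p2, cfg$crossover_rate)
        for (kid in kids) {
          if (k > cfg$pop_size) break
          offspring[[k]] <- evaluate_individual(mutate(kid, g, cfg, eta), ctx)
          k <- k + 1L
        }
      }
      n_evals <- n_evals + cfg$pop_size
      pop <- mu_plus_lambda(pop, offspring, cfg$pop_size)
      fit <- vapply(pop, `[[`, 0, "fitness")
      log <- rbind(log, data.frame(generation = g + 1L, best_f1 = max(fit),
                                   mean_f1 = mean(fit)))
    }
    fit <- vapply(pop, `[[`, 0, "fitness")
    tot <- vapply(pop, `[[`, 0, "total_selected")
    best <- pop[[order(-fit, tot)[1L]]]
    structure(list(best = best,
                   best_phenotype = decode_chromosome(best$bits, layout),
                   log = log, population = pop, cfg = cfg, layout = layout,
                   n_evals = n_evals),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("GA run: %d generations, population %d, %d fitness evaluations\n",
              x$cfg$generations, x$cfg$pop_size, x$n_evals))
  cat(sprintf("  best F1 %.4f with %d feature(s), overlap %d%%, channels {%s}\n",
              x$best$fitness, x$best_phenotype$total_selected,
              x$best_phenotype$overlap_pct,
              paste(x$best_phenotype$active_channels, collapse = ",")))
  invisible(x)
}

#' Pick the best run by analyst criteria
#'
#' Implements the three-step choice of a best solution among runs: validation
#' F1 at least `min_f1`, the required (event-relevant) channels all present,
#' and, among those, the fewest selected features. Falls back to the highest
#' F1 / fewest features when no run satisfies the filters.
#'
#' @param rows data frame with columns `F1`, `total`, and logical
#'   channel-presence columns or a `channels` list column of index vectors.
#' @param required_channels integer indices that must be active.
#' @param min_f1 minimum acceptable F1 (default 0.90).
#' @return The index of the chosen row.
#' @export
pick_best_solution <- function(rows, required_channels = c(1, 2),
                               min_f1 = 0.90) {
  has_req <- vapply(rows$channels, function(ch)
    all(required_channels %in% ch), TRUE)
  ok <- rows$F1 >= min_f1 & has_req
  if (any(ok)) {
    cand <- which(ok)
    cand[order(rows$total[cand], -rows$F1[cand])][1L]
  } else {
    order(-rows$F1, rows$total)[1L]
  }
}
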