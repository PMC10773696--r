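# GA-Boost: per-class decision thresholds learned by a small genetic
# algorithm. The chromosome is one threshold per class in [0, 1); fitness
# is the macro F1 of thresholded decisions. The crossover is the additive
# mod-1 operator; selection is truncation with elitism, which makes the
# best-fitness history provably non-decreasing.

#' Thresholded multiclass decision rule
#'
#' Among classes whose probability reaches its threshold (`p_c >= t_c`),
#' returns the class with the largest margin `p_c - t_c`; when no class
#' qualifies, falls back to the plain argmax of `p`. Ties break toward the
#' lowest class index. With all-equal thresholds this reduces to plain
#' argmax. Set `rule = "raw"` to rank qualifying classes by raw
#' probability instead of margin.
#'
#' @param p probability vector (one sample).
#' @param t threshold vector, same length.
#' @param rule `"margin"` (default) or `"raw"`.
#' @return integer class index.
#' @export
decide <- function(p, t, rule = c("margin", "raw")) {
  rule <- match.arg(rule)
  if (length(p) != length(t))
    stop("probability and threshold lengths differ", call. = FALSE)
  qual <- p >= t
  if (any(qual)) {
    score <- if (rule == "margin") p - t else p
    score[!qual] <- -Inf
    which.max(score)
  } else {
    which.max(p)
  }
}

decide_matrix <- function(probs, t, rule = "margin") {
  vapply(seq_len(nrow(probs)), function(i) decide(probs[i, ], t, rule),
         integer(1))
}

#' Additive mod-1 crossover
#'
#' Element-wise `(X, Y) = ((x + 2y) mod 1, (2x + y) mod 1)`. The integral
#' part is dropped so both children stay in \[0, 1).
#'
#' @param x,y parent threshold vectors of equal length.
#' @return list of two children.
#' @export
ga_crossover <- function(x, y) {
  if (length(x) != length(y)) stop("parent lengths differ", call. = FALSE)
  list((x + 2 * y) %% 1, (2 * x + y) %% 1)
}

#' Uniform resampling mutation
#'
#' Each gene is independently replaced by a fresh uniform \[0, 1) draw
#' with probability `rate`.
#'
#' @param t threshold vector.
#' @param rate mutation probability per gene, in \[0, 1\].
#' @export
ga_mutate <- function(t, rate) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]", call. = FALSE)
  hit <- stats::runif(length(t)) < rate
  t[hit] <- stats::runif(sum(hit))
  t
}

#' Fitness of a threshold vector: macro F1 of thresholded decisions
#'
#' @param t threshold vector.
#' @param probs n x K probability matrix.
#' @param labels integer labels 1..K aligned with rows of `probs`.
#' @param rule decision rule, see [decide()].
#' @export
ga_fitness <- function(t, probs, labels, rule = "margin") {
  if (nrow(probs) != length(labels))
    stop("labels must align with probs rows", call. = FALSE)
  pred <- decide_matrix(probs, t, rule)
  f1_macro(confusion(labels, pred, ncol(probs)))
}

#' GA configuration
#'
#' Defaults follow the published recipe: population of 10 chromosomes,
#' 20% mutation, 20 iterations, elitism on.
#'
#' @param population population size (>= 2).
#' @param mutation_rate per-gene mutation probability.
#' @param iterations number of GA iterations.
#' @param elitism keep the best chromosome unchanged each iteration.
#' @param seed integer seed.
#' @param init `"uniform"` for continuous uniform initialization or
#'   `"grid"` for the discrete \{0.0, 0.1, ..., 0.9\} start.
#' @param rule decision rule passed to [decide()].
#' @export
ga_config <- function(population = 10L, mutation_rate = 0.2, iterations = 20L,
                      elitism = TRUE, seed = 0L, init = c("uniform", "grid"),
                      rule = "margin") {
  if (population < 2L) stop("population must be >= 2", call. = FALSE)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must be in [0, 1]", call. = FALSE)
  list(population = as.integer(population), mutation_rate = mutation_rate,
       iterations = as.integer(iterations), elitism = isTRUE(elitism),
       seed = as.integer(seed), init = match.arg(init), rule = rule)
}

#' Learn per-class thresholds with the genetic algorithm
#'
#' The initial population is drawn uniformly in \[0, 1) per gene (or on
#' the 0.1 grid with `init = "grid"`), plus one seeded baseline chromosome
#' of all 0.5 -- so the returned fitness can never fall below the fixed-0.5
#' baseline. Each iteration ranks the population by fitness, keeps the top
#' half, refills by additive mod-1 crossover of random surviving pairs and
#' mutates the non-elite members. Elitism makes the best-fitness history
#' non-decreasing.
#'
#' @param probs n x K probability matrix (from any classifier emitting
#'   per-class scores in (0,1)).
#' @param labels integer labels 1..K.
#' @param config a [ga_config()].
#' @return list with `thresholds` (best-ever chromosome), `fitness`, and
#'   `history` (per-iteration best fitness, non-decreasing).
#' @export
run_gaboost <- function(probs, labels, config = ga_config()) {
  K <- ncol(probs)
  if (K < 2L) stop("need at least 2 classes", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("degenerate labels: only one class present", call. = FALSE)
  withr_seed(config$seed, {
    pop <- lapply(seq_len(config$population - 1L), function(i) {
      if (config$init == "grid") sample(seq(0, 0.9, by = 0.1), K, replace = TRUE)
      else stats::runif(K)
    })
    pop <- c(pop, list(rep(0.5, K)))   # seeded fixed-threshold baseline
    fit <- vapply(pop, ga_fitness, numeric(1), probs = probs, labels = labels,
                  rule = config$rule)
    best_t <- pop[[which.max(fit)]]
    best_f <- max(fit)
    history <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      ord <- order(fit, decreasing = TRUE)
      keep <- ord[seq_len(max(2L, floor(config$population / 2)))]
      parents <- pop[keep]
      children <- list()
      while (length(parents) + length(children) < config$population) {
        pr <- sample(length(parents), 2L, replace = length(parents) < 2L)
        kids <- ga_crossover(parents[[pr[1]]], parents[[pr[2]]])
        children <- c(children, kids)
      }
      pop <- c(parents, children)[seq_len(config$population)]
      # mutate everything but the elite slot
      first <- if (config$elitism) 2L else 1L
      for (i in first:config$population)
        pop[[i]] <- ga_mutate(pop[[i]], config$mutation_rate)
      fit <- vapply(pop, ga_fitness, numeric(1), probs = probs, labels = labels,
                    rule = config$rule)
      if (max(fit) > best_f) {
        best_f <- max(fit)
        best_t <- pop[[which.max(fit)]]
      }
      history[it] <- best_f
    }
    list(thresholds = best_t, fitness = best_f, history = history)
  })
}
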