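#' Create a table of individuals
#'
#' Individuals are rows of a plain data frame with columns `age` (0 =
#' juvenile, 1 = subadult, 2 = adult), the heritable coefficients `D`, `I`
#' and `U` (logit-scale uninformed trait, expressed only in the evolvable-U
#' variant), `dispersed` (did this individual disperse in the current time
#' step) and `strategy` (attribution of the realized dispersal event:
#' `"none"`, `"uninformed"`, `"density"` or `"immigrant"`).
#'
#' @param n Number of individuals.
#' @param age Age class, recycled.
#' @param D,I,U Heritable coefficients, recycled.
#' @param dispersed,strategy Dispersal bookkeeping, recycled.
#' @return A data frame with one row per individual.
#' @examples
#' new_individuals(3, age = 1)
#' @export
new_individuals <- function(n, age = 0L, D = 0, I = 0, U = stats::qlogis(0.1),
                            dispersed = FALSE, strategy = "none") {
  data.frame(age = rep_len(as.integer(age), n),
             D = rep_len(as.numeric(D), n),
             I = rep_len(as.numeric(I), n),
             U = rep_len(as.numeric(U), n),
             dispersed = rep_len(as.logical(dispersed), n),
             strategy = rep_len(as.character(strategy), n),
             stringsAsFactors = FALSE)
}

#' Create a patch
#'
#' A patch holds its resident individuals, its carrying capacity `K`
#' (enforced at reproduction) and `M`, the count of immigrants that arrived
#' during the current dispersal phase (reset to 0 at the start of every
#' phase).
#'
#' @param id Integer patch index.
#' @param K Carrying capacity.
#' @param residents Data frame of individuals (see [new_individuals()]).
#' @param M Current immigrant count.
#' @return An object of class `patch`.
#' @examples
#' new_patch(1, K = 100, residents = new_individuals(10, age = 1))
#' @export
new_patch <- function(id, K, residents = new_individuals(0), M = 0L) {
  structure(list(id = as.integer(id), K = as.integer(K),
                 residents = residents, M = as.integer(M)),
            class = "patch")
}

#' @export
print.patch <- function(x, ...) {
  cat("<patch ", x$id, "> n = ", nrow(x$residents), " / K = ", x$K,
      ", M = ", x$M, "\n", sep = "")
  invisible(x)
}

#' Survival step for one patch
#'
#' Each resident survives by an independent Bernoulli draw at its
#' age-specific rate: juveniles with probability `s0` (multiplied by
#' `1 - cost` if they dispersed in the previous step), subadults with `s1`,
#' adults with `s2`. Survivors advance one age class (adults stay adults)
#' and their dispersal flags are cleared.
#'
#' @param patch A [new_patch()] object.
#' @param lh A [life_history()] object.
#' @param cost Dispersal cost charged against dispersers' juvenile survival.
#' @return The patch after survival.
#' @examples
#' set.seed(1)
#' p <- new_patch(1, 100, new_individuals(50, age = 0))
#' nrow(survive(p, life_history())$residents)  # ~ 50 * 0.2
#' @export
survive <- function(patch, lh, cost = 0) {
  res <- patch$residents
  n <- nrow(res)
  if (n == 0L) return(patch)
  u <- stats::runif(n)
  p <- ifelse(res$age == 0L,
              lh$s0 * ifelse(res$dispersed, 1 - cost, 1),
              ifelse(res$age == 1L, lh$s1, lh$s2))
  res <- res[u < p, , drop = FALSE]
  if (nrow(res)) {
    res$age <- pmin(res$age + 1L, 2L)
    res$dispersed <- FALSE
    res$strategy <- "none"
  }
  rownames(res) <- NULL
  patch$residents <- res
  patch
}

#' Reproduction step for one patch
#'
#' Every subadult and adult breeds; its offspring count is drawn from a
#' Poisson distribution with mean `f1` (subadults) or `f2` (adults).
#' Offspring are juveniles inheriting the parent's genotype unchanged
#' (mutation is a separate operator, [mutate()]). Total patch size after
#' reproduction is capped at `K`: breeders are processed in a uniformly
#' random order and births beyond the cap are discarded, so no parent is
#' systematically favoured. Offspring are appended after the residents; the
#' number appended is stored in the `"n_offspring"` attribute.
#'
#' @param patch A [new_patch()] object (post-survival census).
#' @param lh A [life_history()] object.
#' @return The patch with offspring appended.
#' @examples
#' set.seed(1)
#' p <- new_patch(1, 100, new_individuals(5, age = 1))
#' attr(reproduce(p, life_history()), "n_offspring")
#' @export
reproduce <- function(patch, lh) {
  res <- patch$residents
  breeders <- which(res$age >= 1L)
  off <- NULL
  if (length(breeders)) {
    ord <- breeders[order(stats::runif(length(breeders)))]
    cur <- nrow(res)
    pieces <- vector("list", length(ord))
    for (j in seq_along(ord)) {
      b <- ord[j]
      k <- stats::rpois(1L, if (res$age[b] == 1L) lh$f1 else lh$f2)
      take <- min(k, patch$K - cur)
      if (take > 0L) {
        pieces[[j]] <- new_individuals(take, age = 0L, D = res$D[b],
                                       I = res$I[b], U = res$U[b])
        cur <- cur + take
      }
    }
    pieces <- pieces[!vapply(pieces, is.null, logical(1))]
    if (length(pieces)) off <- do.call(rbind, pieces)
  }
  n_off <- if (is.null(off)) 0L else nrow(off)
  if (n_off) patch$residents <- rbind(res, off)
  rownames(patch$residents) <- NULL
  attr(patch, "n_offspring") <- n_off
  patch
}

#' Gaussian mutation of heritable coefficients
#'
#' Applied to each offspring immediately after reproduction: each listed
#' locus independently mutates with probability `mutation_prob`, in which
#' case a Gaussian deviate with standard deviation `mutation_sd` is added
#' to the inherited value. Loci are visited row by row in the order given.
#'
#' @param genotype A data frame (or single row) containing the locus
#'   columns.
#' @param mutation_prob Per-locus mutation probability.
#' @param mutation_sd SD of the Gaussian mutation step.
#' @param loci Character vector of locus column names to mutate.
#' @return The genotype table with mutated values.
#' @examples
#' set.seed(1)
#' g <- new_individuals(4)
#' mutate(g, mutation_prob = 1, mutation_sd = 0.02)
#' @export
mutate <- function(genotype, mutation_prob, mutation_sd,
                   loci = c("D", "I")) {
  if (!all(loci %in% names(genotype)))
    stop("mutate: missing locus column(s): ",
         paste(setdiff(loci, names(genotype)), collapse = ", "),
         call. = FALSE)
  nr <- nrow(genotype)
  if (is.null(nr)) nr <- 1L
  if (nr == 0L || mutation_prob <= 0) return(genotype)
  for (i in seq_len(nr)) {
    for (loc in loci) {
      if (stats::runif(1L) < mutation_prob)
        genotype[i, loc] <- genotype[i, loc] +
          stats::rnorm(1L, 0, mutation_sd)
    }
  }
  genotype
}
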