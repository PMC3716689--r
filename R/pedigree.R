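#' Construct a validated pedigree
#'
#' Builds a pedigree object from parallel vectors of animal, sire and dam
#' identifiers plus optional birth years. Unknown parents are encoded as
#' `NA`, `""` or `"0"`. The pedigree is checked for acyclicity (no animal is
#' its own ancestor) and a topological order with parents preceding
#' offspring is stored.
#'
#' @param animal character vector of unique animal ids.
#' @param sire,dam character vectors of parent ids (`NA`/`""`/`"0"` =
#'   unknown founder parent).
#' @param birth_year optional integer vector of birth years (`NA` allowed).
#' @param add_missing_founders if `TRUE`, parents referenced but absent from
#'   `animal` are appended as founder records with unknown parents; if
#'   `FALSE` (default) such references are an error.
#' @return A `data.frame` of class `"pedigree"` with columns `animal`,
#'   `sire`, `dam`, `birth_year`, ordered so that parents precede offspring.
#' @export
pedigree <- function(animal, sire, dam, birth_year = NULL,
                     add_missing_founders = FALSE) {
  animal <- as.character(animal)
  sire <- norm_parent(sire)
  dam <- norm_parent(dam)
  if (anyDuplicated(animal))
    stop("duplicated animal ids: ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  if (is.null(birth_year)) birth_year <- rep(NA_integer_, length(animal))
  birth_year <- as.integer(birth_year)
  stopifnot(length(sire) == length(animal), length(dam) == length(animal),
            length(birth_year) == length(animal))

  referenced <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(referenced)) {
    if (!add_missing_founders)
      stop("parents referenced but not recorded: ",
           paste(referenced, collapse = ", "),
           " (set add_missing_founders = TRUE to treat them as founders)")
    animal <- c(animal, referenced)
    sire <- c(sire, rep(NA_character_, length(referenced)))
    dam <- c(dam, rep(NA_character_, length(referenced)))
    birth_year <- c(birth_year, rep(NA_integer_, length(referenced)))
  }

  ord <- topo_order(animal, sire, dam)
  ped <- data.frame(animal = animal, sire = sire, dam = dam,
                    birth_year = birth_year,
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

norm_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0" | toupper(x) == "NA"] <- NA_character_
  x
}

# Kahn's algorithm; errors with the offending cycle if one exists.
topo_order <- function(animal, sire, dam) {
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- idx[sire]; di <- idx[dam]          # NA for unknown parents
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in idx) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    cyc <- setdiff(idx, out)
    stop("pedigree contains a cycle involving: ",
         paste(animal[cyc], collapse = ", "))
  }
  out
}

#' Read a pedigree from CSV
#'
#' Expects a header `animal,sire,dam,birth_year` (the `birth_year` column is
#' optional). Empty fields, `0` and `NA` denote unknown parents.
#'
#' @param path path to the CSV file.
#' @inheritParams pedigree
#' @return A `"pedigree"` object (see [pedigree()]).
#' @export
read_pedigree <- function(path, add_missing_founders = FALSE) {
  x <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  names(x) <- tolower(names(x))
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(x)))
    stop("pedigree CSV must have columns: animal, sire, dam[, birth_year]")
  by <- if ("birth_year" %in% names(x))
    suppressWarnings(as.integer(x$birth_year)) else NULL
  pedigree(x$animal, x$sire, x$dam, by,
           add_missing_founders = add_missing_founders)
}

#' Numerator relationship matrix from a pedigree
#'
#' Builds the additive (numerator) relationship matrix A by the tabular
#' method: processing animals in an order where parents precede offspring,
#' \eqn{a_{ii} = 1 + 0.5\,a_{sd}} (s, d the parents; an unknown parent
#' contributes 0) and \eqn{a_{ij} = 0.5 (a_{js} + a_{jd})} for previously
#' processed j. Founders are assumed unrelated and non-inbred, so A is
#' symmetric positive semidefinite with diagonal \eqn{1 + F} (F the
#' inbreeding coefficient) and equals twice the kinship matrix.
#'
#' @param ped a `"pedigree"` object.
#' @return A symmetric numeric matrix with dimnames equal to the animal ids.
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (is.na(s)) 0 else A[j, s]
      ad_ <- if (is.na(d)) 0 else A[j, d]
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  A
}

#' Average relationship of candidates to a population
#'
#' For each candidate animal, the mean of its additive-relationship
#' coefficients to every member of the reference population (the vector c of
#' the key-animal selection system).
#'
#' @param A relationship matrix from [relationship_matrix()].
#' @param candidates,population character vectors of animal ids present in
#'   `A`; `population` must be non-empty.
#' @return Named numeric vector, one mean relationship per candidate.
#' @export
average_relationship <- function(A, candidates, population) {
  if (length(population) == 0L) stop("population must be non-empty")
  miss <- setdiff(c(candidates, population), rownames(A))
  if (length(miss))
    stop("animals absent from relationship matrix: ",
         paste(miss, collapse = ", "))
  rowMeans(A[candidates, population, drop = FALSE])
}

#' Proportion of genetic diversity captured by a selected set
#'
#' Solves \eqn{A_m p = c_m} where \eqn{A_m} is the relationship matrix
#' restricted to the m selected animals and \eqn{c_m} their average
#' relationships to the population; p holds the per-animal diversity
#' contributions. The captured proportion is `sum(p)` (default) or the
#' quadratic form \eqn{c_m' A_m^{-1} c_m} (`method = "quadratic"`).
#'
#' Near-singular systems (condition number above `cond_max`, e.g. duplicated
#' individuals) are solved by Moore-Penrose pseudoinverse with a warning.
#'
#' @param A_sub relationship matrix restricted to the selected animals.
#' @param c_sub average-relationship vector for the same animals, in order.
#' @param method aggregation of p into a single proportion.
#' @param cond_max condition-number threshold for the pseudoinverse fallback.
#' @param tol tolerance beyond \[0, 1\] that triggers a clamping warning.
#' @return List with `p` (named contributions) and `proportion` (clamped to
#'   \[0, 1\]).
#' @export
captured_diversity <- function(A_sub, c_sub, method = c("sum", "quadratic"),
                               cond_max = 1e8, tol = 1e-8) {
  method <- match.arg(method)
  A_sub <- as.matrix(A_sub)
  stopifnot(nrow(A_sub) == ncol(A_sub), length(c_sub) == nrow(A_sub))
  p <- solve_relationship(A_sub, c_sub, cond_max)
  names(p) <- rownames(A_sub)
  proportion <- if (method == "sum") sum(p) else sum(c_sub * p)
  if (proportion < -tol || proportion > 1 + tol)
    warning(sprintf("captured proportion %.6g outside [0, 1]; clamped",
                    proportion))
  list(p = p, proportion = min(max(proportion, 0), 1))
}

solve_relationship <- function(A_sub, c_sub, cond_max = 1e8) {
  kap <- kappa(A_sub, exact = nrow(A_sub) <= 64L)
  if (!is.finite(kap) || kap > cond_max) {
    warning(sprintf(
      "relationship submatrix ill-conditioned (condition number %.3g); %s",
      kap, "using pseudoinverse (possible duplicated/cloned animals)"))
    drop(MASS::ginv(A_sub) %*% c_sub)
  } else {
    drop(solve(A_sub, c_sub))
  }
}

#' Iterative selection of key animals
#'
#' Greedy forward selection of the animals capturing the largest proportion
#' of the population's genetic diversity. At each step every remaining
#' candidate is evaluated by re-solving \eqn{A_m p = c_m} for the enlarged
#' set, and the candidate with the highest resulting proportion is added.
#' Ties are broken by earliest birth year, then lexicographically by id.
#' Selection stops early (with a message) if no candidate increases the
#' captured proportion, so the cumulative curve is non-decreasing.
#'
#' @param ped a `"pedigree"` object.
#' @param population animal ids defining the reference population (default:
#'   all animals; optionally restricted by `born_between`).
#' @param candidates animal ids eligible for selection (default: the
#'   population), mirroring restricted DNA availability.
#' @param m_max maximum number of animals to select (positive, at most the
#'   number of candidates).
#' @param born_between optional length-2 numeric vector of birth years;
#'   animals with known birth year outside the range are dropped from the
#'   default population.
#' @param method proportion aggregation, see [captured_diversity()].
#' @param A optional precomputed relationship matrix for `ped`.
#' @return Object of class `"key_selection"`: a list with `selected`
#'   (ordered ids), `p` (contribution vector of the final solve),
#'   `marginal_gain`, `cumulative` (captured proportion after 1..m
#'   selections), and `method`.
#' @export
select_key_animals <- function(ped, population = NULL, candidates = NULL,
                               m_max, born_between = NULL,
                               method = c("sum", "quadratic"), A = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(ped, "pedigree"))
  if (m_max <= 0) stop("m_max must be positive")
  if (is.null(A)) A <- relationship_matrix(ped)
  if (is.null(population)) {
    population <- ped$animal
    if (!is.null(born_between))
      population <- ped$animal[!is.na(ped$birth_year) &
                                 ped$birth_year >= born_between[1] &
                                 ped$birth_year <= born_between[2]]
  }
  if (is.null(candidates)) candidates <- population
  if (!all(candidates %in% ped$animal))
    stop("candidates absent from pedigree: ",
         paste(setdiff(candidates, ped$animal), collapse = ", "))
  if (m_max > length(candidates))
    stop("m_max exceeds the number of candidates")

  cvec <- average_relationship(A, candidates, population)
  by <- ped$birth_year[match(candidates, ped$animal)]
  names(by) <- candidates

  selected <- character(0)
  cumulative <- numeric(0)
  marginal <- numeric(0)
  current <- 0
  remaining <- candidates
  p_final <- NULL

  for (step in seq_len(m_max)) {
    best_prop <- -Inf; best_id <- NULL; best_p <- NULL
    for (cand in remaining) {
      ids <- c(selected, cand)
      res <- captured_diversity(A[ids, ids, drop = FALSE], cvec[ids],
                                method = method)
      better <- res$proportion > best_prop + 1e-12
      tie <- abs(res$proportion - best_prop) <= 1e-12
      if (better || (tie && tie_beats(cand, best_id, by))) {
        best_prop <- res$proportion; best_id <- cand; best_p <- res$p
      }
    }
    if (best_prop <= current + 1e-12) {
      message(sprintf(
        "no candidate increases the captured proportion; stopping after %d of %d selections",
        step - 1L, m_max))
      break
    }
    selected <- c(selected, best_id)
    marginal <- c(marginal, best_prop - current)
    cumulative <- c(cumulative, best_prop)
    current <- best_prop
    p_final <- best_p
    remaining <- setdiff(remaining, best_id)
  }

  structure(list(selected = selected, p = p_final,
                 marginal_gain = stats::setNames(marginal, selected),
                 cumulative = stats::setNames(cumulative, selected),
                 population = population, method = method),
            class = "key_selection")
}

# earlier birth year wins; unknown years sort last; then lexicographic id
tie_beats <- function(cand, best, by) {
  if (is.null(best)) return(TRUE)
  a <- by[cand]; b <- by[best]
  if (is.na(a) && !is.na(b)) return(FALSE)
  if (!is.na(a) && is.na(b)) return(TRUE)
  if (!is.na(a) && !is.na(b) && a != b) return(a < b)
  cand < best
}

#' @export
print.key_selection <- function(x, ...) {
  cat(sprintf("Key-animal selection (%d animals, method = %s)\n",
              length(x$selected), x$method))
  cat(sprintf("Captured proportion of genetic diversity: %.4f\n",
              utils::tail(x$cumulative, 1)))
  df <- data.frame(rank = seq_along(x$selected), animal = x$selected,
                   marginal_gain = unname(x$marginal_gain),
                   cumulative = unname(x$cumulative))
  print(utils::head(df, 20), row.names = FALSE)
  if (nrow(df) > 20) cat("...", nrow(df) - 20, "more\n")
  invisible(x)
}

#' @export
summary.key_selection <- function(object, ...) {
  data.frame(rank = seq_along(object$selected), animal = object$selected,
             marginal_gain = unname(object$marginal_gain),
             cumulative_proportion = unname(object$cumulative),
             final_p = unname(object$p[object$selected]))
}

#' @export
plot.key_selection <- function(x, ...) {
  plot(seq_along(x$cumulative), x$cumulative, type = "b", pch = 19,
       xlab = "number of selected animals",
       ylab = "captured proportion of genetic diversity",
       ylim = c(0, max(1, x$cumulative)), ...)
  invisible(x)
}
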