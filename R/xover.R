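## Unequal crossing-over between motif arrays.
##
## Breakpoints are motif-granular: recombination is modelled between motifs,
## in the register imposed by the shared 10-nt motif head, because observed
## population alleles are mosaics of whole motifs and sub-motif breakpoints
## would create repeat units never seen in the locus. No replication
## slippage / stepwise mutation is modelled: the locus is stable across
## generations, in contrast to dynamic-mutation loci, and the model reflects
## that by making unequal exchange the only mutational force.

#' Unequal crossing-over between two motif arrays
#'
#' Splices \code{p1[0:break1]} onto \code{p2[break2:n2]} and vice versa
#' (0-based breakpoints between motifs, \code{0 <= break_k <= n_k}). Total
#' motif count is conserved across the two products; the exchange is unequal
#' iff \code{break1 != break2}. Insertion-bearing parents are rejected
#' (non-motif segments block the motif-register misalignment the model
#' assumes).
#'
#' @param p1,p2 Insertion-free \linkS4class{AlleleStructure} parents.
#' @param break1,break2 0-based breakpoints (motif index counts retained from
#'   the 5' side of each parent).
#' @return List of two \linkS4class{AlleleStructure} products (either may have
#'   zero motifs; viability is enforced by callers).
#' @examples
#' p <- alleleStructure(rep("CACA20", 7))
#' unequalCrossover(p, p, 2, 5)
#' @export
unequalCrossover <- function(p1, p2, break1, break2) {
  if (hasInsertions(p1) || hasInsertions(p2))
    stop("insertion-bearing parents are not recombined")
  n1 <- repeatCount(p1); n2 <- repeatCount(p2)
  if (break1 < 0L || break1 > n1 || break2 < 0L || break2 > n2)
    stop("breakpoints must satisfy 0 <= break1 <= ", n1,
         " and 0 <= break2 <= ", n2)
  m1 <- p1@motifs; m2 <- p2@motifs
  q1 <- c(m1[seq_len(break1)], m2[seq_len(n2 - break2) + break2])
  q2 <- c(m2[seq_len(break2)], m1[seq_len(n1 - break1) + break1])
  list(alleleStructure(q1), alleleStructure(q2))
}

## All (break1, break2, product) choices for an unequal exchange whose chosen
## product size lies in the viable range.
.valid_xover_choices <- function(n1, n2, viable) {
  out <- list()
  for (b1 in 0:n1) for (b2 in 0:n2) {
    if (b1 == b2) next
    s1 <- b1 + (n2 - b2)   # size of product 1
    s2 <- b2 + (n1 - b1)
    if (s1 >= viable[1] && s1 <= viable[2])
      out[[length(out) + 1L]] <- c(b1, b2, 1L)
    if (s2 >= viable[1] && s2 <= viable[2])
      out[[length(out) + 1L]] <- c(b1, b2, 2L)
  }
  out
}

#' Wright-Fisher evolution of a repeat-allele pool under unequal crossover
#'
#' Evolves a diploid population of constant size by Wright-Fisher resampling.
#' Each transmitted allele is, with probability \code{crossoverRate}, a
#' product of unequal crossing-over between the parent's two homologs, with
#' the (break1, break2, product) choice uniform over misaligned pairings
#' (\code{|break1 - break2| >= 1}) whose product size falls in
#' \code{viableRange} (2-20 motifs by default: the observed viable range 2-17
#' plus headroom). With \code{crossoverRate = 0} allele structures are
#' immutable and the spectrum changes only by drift.
#'
#' @param initialPool List of insertion-free \linkS4class{AlleleStructure}
#'   objects (or nomenclature strings), recycled to \code{2 * popSize}.
#' @param popSize Number of diploid individuals.
#' @param generations Number of generations to simulate.
#' @param crossoverRate Per-transmission unequal-crossover probability in
#'   [0, 1].
#' @param viableRange Length-2 integer vector of viable product sizes.
#' @param seed Integer seed controlling the whole trajectory.
#' @return A list with \code{pools} (per-generation character vectors of
#'   allele nomenclatures, generation 0 first), \code{events} (data.frame log:
#'   generation, parent1, parent2, break1, break2, product), and
#'   \code{params}.
#' @export
evolvePopulation <- function(initialPool, popSize, generations,
                             crossoverRate, viableRange = c(2L, 20L),
                             seed = 1L) {
  if (popSize < 1L) stop("popSize must be positive")
  if (crossoverRate < 0 || crossoverRate > 1)
    stop("crossoverRate must be in [0, 1]")
  pool <- lapply(initialPool, function(a)
    if (is.character(a)) parseAlleleName(a) else a)
  if (any(vapply(pool, hasInsertions, logical(1))))
    stop("initial pool must be insertion-free")
  pool <- lapply(pool, motifs)
  pool <- rep(pool, length.out = 2L * popSize)

  set.seed(seed)
  pools <- vector("list", generations + 1L)
  pools[[1]] <- vapply(pool, function(m) alleleName(alleleStructure(m)),
                       character(1))
  ev <- list()

  for (g in seq_len(generations)) {
    nxt <- vector("list", 2L * popSize)
    for (child in seq_len(popSize)) {
      for (side in 1:2) {
        parent <- sample.int(popSize, 1L)
        h1 <- pool[[2L * parent - 1L]]
        h2 <- pool[[2L * parent]]
        transmitted <- NULL
        if (runif(1) < crossoverRate) {
          choices <- .valid_xover_choices(length(h1), length(h2), viableRange)
          if (length(choices)) {
            ch <- choices[[sample.int(length(choices), 1L)]]
            pr <- unequalCrossover(alleleStructure(h1), alleleStructure(h2),
                                   ch[1], ch[2])
            transmitted <- motifs(pr[[ch[3]]])
            ev[[length(ev) + 1L]] <- data.frame(
              generation = g,
              parent1 = alleleName(alleleStructure(h1)),
              parent2 = alleleName(alleleStructure(h2)),
              break1 = ch[1], break2 = ch[2], product = ch[3],
              result = alleleName(alleleStructure(transmitted)),
              stringsAsFactors = FALSE)
          }
        }
        if (is.null(transmitted))
          transmitted <- if (runif(1) < 0.5) h1 else h2
        nxt[[2L * (child - 1L) + side]] <- transmitted
      }
    }
    pool <- nxt
    pools[[g + 1L]] <- vapply(pool, function(m) alleleName(alleleStructure(m)),
                              character(1))
  }

  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(generation = integer(0), parent1 = character(0),
               parent2 = character(0), break1 = integer(0),
               break2 = integer(0), product = integer(0),
               result = character(0))
  list(pools = pools, events = events,
       params = list(popSize = popSize, generations = generations,
                     crossoverRate = crossoverRate,
                     viableRange = viableRange, seed = seed))
}

#' Minimal unequal-crossover derivation of a target allele from a pool
#'
#' Breadth-first search for the smallest number of unequal crossing-over
#' events deriving \code{target} from \code{pool}: level-k products are
#' crossovers between any two alleles of the accumulated set (pool plus
#' earlier products), restricted to misaligned pairings in the motif-head
#' register with products in \code{viableRange}. Exact within
#' \code{maxEvents}.
#'
#' @param target Insertion-free \linkS4class{AlleleStructure} (or nomenclature
#'   string).
#' @param pool List of insertion-free structures or nomenclature strings.
#' @param maxEvents Search depth bound (kept small; the search is
#'   exponential).
#' @param viableRange Viable product sizes.
#' @param nodeBudget Abort threshold on distinct structures explored.
#' @return A list with \code{minEvents} (integer, or NA when unreachable
#'   within \code{maxEvents}), \code{reachable} flag, and \code{witness}: a
#'   data.frame of events (parent1, parent2, break1, break2, product, result)
#'   realizing one minimal path.
#' @export
derivationDistance <- function(target, pool, maxEvents = 2L,
                               viableRange = c(2L, 20L),
                               nodeBudget = 200000L) {
  tgt <- if (is.character(target)) parseAlleleName(target) else target
  if (hasInsertions(tgt)) stop("target must be insertion-free")
  tname <- alleleName(tgt)
  pool <- lapply(pool, function(a)
    if (is.character(a)) parseAlleleName(a) else a)
  pnames <- vapply(pool, alleleName, character(1))

  if (tname %in% pnames)
    return(list(minEvents = 0L, reachable = TRUE,
                witness = data.frame(parent1 = character(0),
                                     parent2 = character(0),
                                     break1 = integer(0), break2 = integer(0),
                                     product = integer(0),
                                     result = character(0))))

  seen <- new.env(parent = emptyenv())       # name -> list(level, via)
  mcache <- new.env(parent = emptyenv())     # name -> motif vector
  fast_name <- function(m) {
    r <- rle(m)
    paste(ifelse(r$lengths > 1L, paste0(r$lengths, "x", r$values),
                 r$values), collapse = "+")
  }
  for (i in seq_along(pool)) {
    nm <- pnames[i]
    if (!exists(nm, seen, inherits = FALSE)) {
      assign(nm, list(level = 0L, via = NULL), seen)
      assign(nm, motifs(pool[[i]]), mcache)
    }
  }
  frontier <- unique(pnames)
  all_names <- frontier
  n_seen <- length(frontier)

  for (lvl in seq_len(maxEvents)) {
    new_frontier <- character(0)
    # cross every accumulated structure with the previous frontier; products
    # of both orders are covered by the two breakpoint roles
    for (a in all_names) for (b in frontier) {
      ma <- get(a, mcache); mb <- get(b, mcache)
      n1 <- length(ma); n2 <- length(mb)
      for (b1 in 0:n1) for (b2 in 0:n2) {
        if (b1 == b2) next
        for (pi in 1:2) {
          n <- if (pi == 1L) b1 + (n2 - b2) else b2 + (n1 - b1)
          if (n < viableRange[1] || n > viableRange[2]) next
          q <- if (pi == 1L) c(ma[seq_len(b1)], mb[seq_len(n2 - b2) + b2])
               else c(mb[seq_len(b2)], ma[seq_len(n1 - b1) + b1])
          nm <- fast_name(q)
          if (!exists(nm, seen, inherits = FALSE)) {
            assign(nm, list(level = lvl,
                            via = list(parent1 = a, parent2 = b,
                                       break1 = b1, break2 = b2,
                                       product = pi)), seen)
            assign(nm, q, mcache)
            new_frontier <- c(new_frontier, nm)
            n_seen <- n_seen + 1L
            if (n_seen > nodeBudget)
              stop("derivation search exceeded node budget (frontier size ",
                   length(new_frontier), ")")
            if (nm == tname) {
              return(list(minEvents = lvl, reachable = TRUE,
                          witness = .trace_witness(seen, tname)))
            }
          }
        }
      }
    }
    if (length(new_frontier) == 0L) break
    frontier <- new_frontier
    all_names <- c(all_names, new_frontier)
  }
  list(minEvents = NA_integer_, reachable = FALSE, witness = NULL)
}

.trace_witness <- function(seen, name) {
  rows <- list()
  walk <- function(nm) {
    node <- get(nm, seen, inherits = FALSE)
    if (is.null(node$via)) return(invisible())
    walk(node$via$parent1)
    walk(node$via$parent2)
    rows[[length(rows) + 1L]] <<- data.frame(
      parent1 = node$via$parent1, parent2 = node$via$parent2,
      break1 = node$via$break1, break2 = node$via$break2,
      product = node$via$product, result = nm, stringsAsFactors = FALSE)
  }
  walk(name)
  unique(do.call(rbind, rows))
}
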