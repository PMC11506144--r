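# Gamete formation and F1 population construction.  Each chromosome of
# each gamete receives 4-6 crossovers (uniform over {4,5,6}), positions
# uniform over the marker-index range by default; one generation only, no
# mutation, no interference beyond the fixed count range.

#' Draw per-chromosome crossover counts
#'
#' @param n Number of draws.
#' @param seed Optional seed.
#' @return Integer vector with values uniform on \{4, 5, 6\}.
#' @export
sample_crossover_count <- function(n = 1, seed = NULL) {
  with_seed(seed, sample(4:6, n, replace = TRUE))
}

#' Build a sire-dam mating design
#'
#' Assigns every dam to exactly one sire, each sire serving
#' \code{dams_per_sire} dams (default 1:24 sire:dam ratio), with dams
#' allocated to sires in shuffled blocks.
#'
#' @param panel A sexed \code{hap_panel}; all males become sires, all
#'   females dams.
#' @param dams_per_sire Dams served by each sire (default 24).
#' @param offspring_per_dam Litter size per dam (default 12).
#' @param seed Optional seed for the dam shuffle.
#' @return A \code{mating_design}: list with \code{sires}, \code{dams},
#'   \code{dam_sire} (named vector mapping dam to sire) and
#'   \code{offspring_per_dam}.
#' @export
mating_design <- function(panel, dams_per_sire = 24, offspring_per_dam = 12,
                          seed = NULL) {
  stopifnot(inherits(panel, "hap_panel"))
  sires <- panel$ids[panel$sex == "M"]
  dams <- panel$ids[panel$sex == "F"]
  if (length(sires) < 1) stop("no male founders available as sires")
  if (length(dams) != dams_per_sire * length(sires))
    stop(sprintf(
      "design infeasible: %d dams cannot be split as %d per each of %d sires",
      length(dams), dams_per_sire, length(sires)))
  with_seed(seed, {
    shuffled <- sample(dams)
    dam_sire <- stats::setNames(rep(sires, each = dams_per_sire), shuffled)
    structure(list(sires = sires, dams = shuffled,
                   dam_sire = dam_sire,
                   offspring_per_dam = as.integer(offspring_per_dam)),
              class = "mating_design")
  })
}

#' Form one gamete from a pair of parental haplotypes
#'
#' The gamete copies from one parental haplotype and switches source after
#' each crossover position (position \eqn{p} means a switch between markers
#' \eqn{p} and \eqn{p+1}).  When positions are not supplied, their count is
#' drawn from \{4, 5, 6\} and their locations uniformly over the
#' marker-index range.
#'
#' @param hap_a,hap_b Equal-length 0/1 parental haplotypes.
#' @param crossovers Optional strictly increasing integer positions in
#'   \code{1:(length(hap_a) - 1)}; may be \code{integer(0)} to force an
#'   intact gamete.
#' @param start_on_a Optional logical: start copying from \code{hap_a}?
#'   Defaults to a fair coin flip.
#' @param seed Optional seed.
#' @return Integer 0/1 gamete haplotype.
#' @export
make_gamete <- function(hap_a, hap_b, crossovers = NULL, start_on_a = NULL,
                        seed = NULL) {
  m <- length(hap_a)
  if (length(hap_b) != m) stop("parental haplotypes differ in length")
  with_seed(seed, {
    if (is.null(crossovers)) {
      ncx <- sample(4:6, 1L)
      if (ncx > m - 1L) stop("chromosome too short for the crossover count")
      crossovers <- sort(sample.int(m - 1L, ncx))
    } else if (length(crossovers)) {
      crossovers <- as.integer(crossovers)
      if (any(crossovers < 1L | crossovers > m - 1L))
        stop("crossover positions out of range 1:(m-1)")
      if (any(diff(crossovers) <= 0L))
        stop("crossover positions must be strictly increasing")
    }
    if (is.null(start_on_a)) start_on_a <- stats::runif(1) < 0.5
    src <- integer(m)                       # 0 = hap_a, 1 = hap_b
    if (length(crossovers)) src[crossovers + 1L] <- 1L
    src <- (cumsum(src) + as.integer(!start_on_a)) %% 2L
    as.integer(ifelse(src == 0L, hap_a, hap_b))
  })
}

# Vectorised gamete formation for one chromosome: builds `ng` gametes from
# the rows of the parental haplotype matrices selected by `parent_idx`.
# Returns an ng-by-m integer matrix.
gametes_chromosome <- function(hap1, hap2, parent_idx, cols,
                               scale = c("rank", "bp"), bp = NULL) {
  scale <- match.arg(scale)
  m <- length(cols)
  ng <- length(parent_idx)
  ncx <- sample(4:6, ng, replace = TRUE)
  sw <- vector("list", ng)
  for (g in seq_len(ng)) {
    if (scale == "rank") {
      sw[[g]] <- sample.int(m - 1L, ncx[g])
    } else {
      u <- stats::runif(ncx[g], bp[1L], bp[m])
      p <- findInterval(u, bp)
      p <- p[p >= 1L & p <= m - 1L]
      tab <- table(p)                      # two crossovers in one marker
      sw[[g]] <- as.integer(names(tab)[tab %% 2L == 1L])  # interval cancel
    }
  }
  start <- stats::rbinom(ng, 1L, 0.5)      # 0 = start on hap1
  C <- matrix(0L, m, ng)
  idx <- unlist(sw, use.names = FALSE) + 1L +
    rep((seq_len(ng) - 1L) * m, times = lengths(sw))
  C[idx] <- 1L
  cs <- cumsum(C)
  base <- c(0, cs[m * seq_len(ng - 1L)])
  colcum <- cs - rep(base, each = m)
  src <- (colcum + rep(start, each = m)) %% 2L
  A <- t(hap1[parent_idx, cols, drop = FALSE])
  B <- t(hap2[parent_idx, cols, drop = FALSE])
  t(matrix(ifelse(src == 0L, A, B), m, ng))
}

#' Simulate the F1 generation under a mating design
#'
#' Every offspring receives one maternal and one paternal gamete per
#' chromosome; each gamete of each chromosome uses an independently drawn
#' crossover count from \{4, 5, 6\}.  No mutation is applied, so every
#' offspring allele exists in a parent at the same locus.
#'
#' @param founders Sexed founder \code{hap_panel}.
#' @param design A \code{\link{mating_design}}.
#' @param seed Optional seed.
#' @param crossover_scale \code{"rank"} (positions uniform over marker
#'   indices, default) or \code{"bp"} (uniform over physical positions).
#' @return List with \code{panel} (offspring \code{hap_panel}; maternal
#'   gamete in \code{hap1}, paternal in \code{hap2}) and \code{pedigree}
#'   (data frame \code{id}, \code{sire}, \code{dam}).
#' @export
build_f1 <- function(founders, design, seed = NULL,
                     crossover_scale = c("rank", "bp")) {
  stopifnot(inherits(founders, "hap_panel"),
            inherits(design, "mating_design"))
  crossover_scale <- match.arg(crossover_scale)
  parents <- c(design$sires, design$dams)
  missing_p <- setdiff(parents, founders$ids)
  if (length(missing_p))
    stop("design references unknown parents: ",
         paste(utils::head(missing_p, 3), collapse = ", "))
  opd <- design$offspring_per_dam
  dams_off <- rep(design$dams, each = opd)
  sires_off <- unname(design$dam_sire[dams_off])
  n_off <- length(dams_off)
  ids_off <- sprintf("C%0*d", nchar(n_off), seq_len(n_off))
  dam_idx <- match(dams_off, founders$ids)
  sire_idx <- match(sires_off, founders$ids)

  with_seed(seed, {
    m_tot <- nrow(founders$map)
    hap_m <- matrix(0L, n_off, m_tot)
    hap_p <- matrix(0L, n_off, m_tot)
    for (cc in unique(founders$map$chrom)) {
      cols <- which(founders$map$chrom == cc)
      bp <- founders$map$bp[cols]
      hap_m[, cols] <- gametes_chromosome(founders$hap1, founders$hap2,
                                          dam_idx, cols, crossover_scale, bp)
      hap_p[, cols] <- gametes_chromosome(founders$hap1, founders$hap2,
                                          sire_idx, cols, crossover_scale, bp)
    }
    sex_off <- sample(c("M", "F"), n_off, replace = TRUE)
    panel <- new_hap_panel(ids_off, sex_off, hap_m, hap_p, founders$map)
    list(panel = panel,
         pedigree = data.frame(id = ids_off, sire = sires_off,
                               dam = dams_off, stringsAsFactors = FALSE))
  })
}

#' Sample selection candidates from the F1 population
#'
#' @param f1_panel F1 \code{hap_panel} (or a character vector of ids).
#' @param n Number of candidates (default 2000).
#' @param seed Optional seed.
#' @return Character vector of \code{n} unique candidate ids.
#' @export
sample_candidates <- function(f1_panel, n = 2000, seed = NULL) {
  ids <- if (inherits(f1_panel, "hap_panel")) f1_panel$ids else f1_panel
  if (n > length(ids))
    stop(sprintf("cannot sample %d candidates from %d offspring",
                 n, length(ids)))
  with_seed(seed, sample(ids, n))
}
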