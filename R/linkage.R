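#' Screen genotypes for Mendelian inheritance errors
#'
#' Offspring genotypes incompatible with the parental pair are set to
#' missing and reported. With a missing parent only the genotyped parent
#' constrains transmission (e.g. AA x ? with offspring BB is an error: the
#' AA parent cannot transmit B).
#'
#' @param ped PED-like `data.frame` (see [simulateFamilyGenotypes()]):
#'   columns `family`, `id`, `sire`, `dam`, then genotype columns with
#'   values `"AA"/"AB"/"BB"/NA`.
#' @return `list(ped, errors)`: the cleaned table and a `data.frame`
#'   (`family`, `id`, `marker`) of flagged genotypes.
#' @export
mendelianCheck <- function(ped) {
  markerCols <- setdiff(names(ped), c("family", "id", "sire", "dam"))
  alleles <- list(AA = c("A", "A"), AB = c("A", "B"), BB = c("B", "B"))
  canTransmit <- function(parentG, allele) {
    is.na(parentG) | vapply(seq_along(parentG), function(i) {
      if (is.na(parentG[i])) TRUE else allele[i] %in% alleles[[parentG[i]]]
    }, logical(1))
  }
  errors <- list()
  offspring <- which(ped$sire != "0" | ped$dam != "0")
  for (m in markerCols) {
    g <- ped[[m]]
    for (o in offspring) {
      go <- g[o]
      if (is.na(go)) next
      gs <- g[match(ped$sire[o], ped$id)]
      gd <- g[match(ped$dam[o], ped$id)]
      a <- alleles[[go]]
      ok <- (canTransmit(gs, a[1]) && canTransmit(gd, a[2])) ||
            (canTransmit(gs, a[2]) && canTransmit(gd, a[1]))
      if (!ok) {
        errors[[length(errors) + 1L]] <-
          data.frame(family = ped$family[o], id = ped$id[o], marker = m,
                     stringsAsFactors = FALSE)
        ped[o, m] <- NA
      }
    }
  }
  list(ped = ped,
       errors = if (length(errors)) do.call(rbind, errors) else
         data.frame(family = character(), id = character(),
                    marker = character()))
}

# Per-parent transmitted-allele matrices: for every (family, parent),
# a matrix offspring x markers with 0 = transmitted A, 1 = transmitted B,
# NA = not deducible (parent homozygous/missing at the marker, offspring
# missing, or the fully ambiguous AB x AB -> AB configuration).
.transmissions <- function(ped, markers) {
  fams <- unique(ped$family[ped$sire != "0"])
  out <- list()
  for (f in fams) {
    off <- ped[ped$family == f & ped$sire != "0", , drop = FALSE]
    if (nrow(off) == 0) next
    sireId <- unique(off$sire); damId <- unique(off$dam)
    if (length(sireId) != 1L || length(damId) != 1L)
      stop("each family must be a single full-sib cross")
    for (par in c("sire", "dam")) {
      pid <- if (par == "sire") sireId else damId
      oid <- if (par == "sire") damId else sireId
      pg <- unlist(ped[match(pid, ped$id), markers])
      og <- unlist(ped[match(oid, ped$id), markers])
      tm <- matrix(NA_integer_, nrow(off), length(markers),
                   dimnames = list(off$id, markers))
      for (j in seq_along(markers)) {
        if (is.na(pg[j]) || pg[j] != "AB") next  # uninformative parent
        gc <- off[[markers[j]]]
        v <- rep(NA_integer_, length(gc))
        v[gc == "AA"] <- 0L
        v[gc == "BB"] <- 1L
        het <- which(gc == "AB")
        if (length(het) > 0 && !is.na(og[j])) {
          if (og[j] == "AA") v[het] <- 1L   # other parent gave A
          if (og[j] == "BB") v[het] <- 0L
        }
        tm[, j] <- v
      }
      out[[paste(f, par, sep = ".")]] <- tm
    }
  }
  out
}

# phase-resolved recombinant / informative counts for one marker pair
.pairRN <- function(trans, i, j) {
  R <- 0L; N <- 0L
  for (tm in trans) {
    ok <- !is.na(tm[, i]) & !is.na(tm[, j])
    n <- sum(ok)
    if (n == 0L) next
    s <- sum(tm[ok, i] != tm[ok, j])
    # parental phase chosen by maximizing the two-point likelihood,
    # equivalent to taking the minority count as recombinant
    R <- R + min(s, n - s)
    N <- N + n
  }
  c(R = R, N = N)
}

.lodFromRN <- function(R, N) {
  R <- unname(R); N <- unname(N)
  theta <- min(R / N, 0.5)
  if (theta >= 0.5) return(c(theta = 0.5, lod = 0))
  ll <- if (R == 0) (N - R) * log10(1 - theta) else
    R * log10(theta) + (N - R) * log10(1 - theta)
  c(theta = theta, lod = ll - N * log10(0.5))
}

#' Two-point linkage between two markers
#'
#' Phase is resolved per parent by maximizing the two-point likelihood over
#' both phases (equivalently, the minority transmission class is counted as
#' recombinant). With `R` recombinants among `N` informative meioses,
#' `theta = min(R/N, 0.5)` and
#' `LOD = log10( theta^R (1-theta)^(N-R) / 0.5^N )` at `theta < 0.5`, else
#' 0. Fully ambiguous AB x AB -> AB meioses contribute no information.
#'
#' @param markerA,markerB Marker (column) names.
#' @param ped PED-like genotype table.
#' @return One-row `data.frame`: `marker_a`, `marker_b`, `theta`, `lod`,
#'   `n_informative`; `NULL` when there is no informative meiosis.
#' @export
twopoint <- function(markerA, markerB, ped) {
  trans <- .transmissions(ped, c(markerA, markerB))
  rn <- .pairRN(trans, 1L, 2L)
  if (rn["N"] == 0L) return(NULL)
  tl <- .lodFromRN(rn["R"], rn["N"])
  data.frame(marker_a = markerA, marker_b = markerB,
             theta = unname(tl["theta"]), lod = unname(tl["lod"]),
             n_informative = unname(rn["N"]), stringsAsFactors = FALSE)
}

#' All-pairs two-point linkage
#'
#' @param ped PED-like genotype table.
#' @param markersA Markers to compare (default: all genotype columns).
#' @param markersB Second marker set; default `markersA` (all unordered
#'   pairs within the set). When given, all cross pairs are computed.
#' @return `data.frame` of [twopoint()] rows (pairs without informative
#'   meioses are absent).
#' @export
twopointAll <- function(ped, markersA = NULL, markersB = NULL) {
  allMarkers <- setdiff(names(ped), c("family", "id", "sire", "dam"))
  if (is.null(markersA)) markersA <- allMarkers
  cross <- !is.null(markersB)
  markers <- unique(c(markersA, if (cross) markersB))
  trans <- .transmissions(ped, markers)
  res <- list()
  if (cross) {
    pairs <- expand.grid(a = markersA, b = markersB,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  } else {
    if (length(markersA) < 2L)
      return(data.frame(marker_a = character(), marker_b = character(),
                        theta = numeric(), lod = numeric(),
                        n_informative = integer()))
    cmb <- utils::combn(markersA, 2L)
    pairs <- data.frame(a = cmb[1, ], b = cmb[2, ],
                        stringsAsFactors = FALSE)
  }
  ia <- match(pairs$a, markers); ib <- match(pairs$b, markers)
  for (k in seq_len(nrow(pairs))) {
    rn <- .pairRN(trans, ia[k], ib[k])
    if (rn["N"] == 0L) next
    tl <- .lodFromRN(rn["R"], rn["N"])
    res[[length(res) + 1L]] <- data.frame(
      marker_a = pairs$a[k], marker_b = pairs$b[k],
      theta = unname(tl["theta"]), lod = unname(tl["lod"]),
      n_informative = unname(rn["N"]), stringsAsFactors = FALSE)
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(marker_a = character(), marker_b = character(),
               theta = numeric(), lod = numeric(),
               n_informative = integer())
}

#' Assign an unmapped marker to a chromosome by two-point support
#'
#' A marker is assigned to a chromosome when at least `minSupport` mapped
#' markers on it show linkage above `lodThreshold` and no other chromosome
#' qualifies; two qualifying chromosomes leave the marker unassigned with a
#' conflict flag.
#'
#' @param results Two-point results with `marker_a` = unmapped,
#'   `marker_b` = mapped markers (see [twopointAll()]).
#' @param markerIndex `data.frame` with `marker`, `chrom` of the mapped
#'   markers.
#' @param lodThreshold LOD threshold (default 4, strict `>`).
#' @param minSupport Minimum qualifying markers on the chromosome
#'   (default 2: "multiple").
#' @return `data.frame` per unmapped marker: `marker`, `chrom` (`NA` when
#'   unassigned), `n_support`, `conflict`.
#' @export
assignToChromosome <- function(results, markerIndex, lodThreshold = 4,
                               minSupport = 2) {
  out <- list()
  for (m in unique(results$marker_a)) {
    r <- results[results$marker_a == m & results$lod > lodThreshold, ,
                 drop = FALSE]
    chrom <- markerIndex$chrom[match(r$marker_b, markerIndex$marker)]
    tab <- table(chrom[!is.na(chrom)])
    qual <- names(tab)[tab >= minSupport]
    out[[m]] <- data.frame(
      marker = m,
      chrom = if (length(qual) == 1L) qual else NA_character_,
      n_support = if (length(qual) >= 1L) max(tab) else
        if (length(tab)) max(tab) else 0L,
      conflict = length(qual) > 1L,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Construct new linkage groups from unassigned markers
#'
#' Builds the graph whose edges are marker pairs with LOD strictly above
#' the threshold and returns its connected components of size >= 2
#' (singletons are not groups). Groups are labelled `LG1`, `LG2`, ... by
#' decreasing size, ties by smallest member id.
#'
#' @param results All-vs-all two-point results among the unassigned
#'   markers.
#' @param markers The unassigned marker ids (vertices; markers without any
#'   qualifying edge become singletons and are dropped).
#' @param lodThreshold LOD threshold (default 4, strict `>`).
#' @return Named list of character vectors (members per group, sorted).
#' @export
buildNewGroups <- function(results, markers = NULL, lodThreshold = 4) {
  edges <- results[!is.na(results$lod) & results$lod > lodThreshold,
                   c("marker_a", "marker_b"), drop = FALSE]
  if (is.null(markers))
    markers <- unique(c(results$marker_a, results$marker_b))
  if (nrow(edges) == 0) return(list())
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = unique(markers))
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- Filter(function(x) length(x) >= 2L, groups)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups),
               vapply(groups, function(x) x[1], ""))
  groups <- groups[ord]
  names(groups) <- sprintf("LG%d", seq_along(groups))
  groups
}

#' Kosambi map function and its inverse
#'
#' `kosambiCm(theta) = 25 * ln((1 + 2 theta) / (1 - 2 theta))` converts a
#' recombination fraction to centiMorgans under partial crossover
#' interference; `kosambiTheta()` inverts it
#' (`theta = tanh(d / 50) / 2`).
#'
#' @param theta Recombination fraction(s) in \[0, 0.5).
#' @param cm Map distance(s) in cM, >= 0.
#' @return Numeric vector.
#' @examples
#' kosambiCm(0.1)   # 10.137
#' kosambiCm(0.25)  # 27.465
#' @export
kosambiCm <- function(theta) {
  if (any(theta < 0 | theta >= 0.5, na.rm = TRUE))
    stop("theta must lie in [0, 0.5)")
  25 * log((1 + 2 * theta) / (1 - 2 * theta))
}

#' @rdname kosambiCm
#' @export
kosambiTheta <- function(cm) {
  if (any(cm < 0)) stop("cm must be >= 0")
  tanh(cm / 50) / 2
}

#' Order a linkage group by two-point distances
#'
#' Greedy two-point ordering: the most distant confident pair (largest
#' theta among pairs with LOD >= `anchorLod`, falling back to all pairs)
#' anchors the two map ends; the remaining markers are ordered by their
#' recombination fraction to the first anchor. Adjacent distances are the
#' Kosambi transform of the adjacent-pair theta estimates (NA when a pair
#' was uninformative or unlinked). Two-point greedy ordering is coarser
#' than multipoint likelihood ordering; map lengths will differ from a
#' multipoint map.
#'
#' @param members Marker ids of the group (length >= 2).
#' @param results Two-point results covering the group's pairs.
#' @param anchorLod Confidence threshold for anchor pairs (default 3).
#' @return `data.frame` in map order: `marker`, `theta_prev`, `cm_prev`,
#'   `cum_cm`.
#' @export
orderGroup <- function(members, results, anchorLod = 3) {
  stopifnot(length(members) >= 2L)
  r <- results[results$marker_a %in% members &
               results$marker_b %in% members, , drop = FALSE]
  conf <- r[r$lod >= anchorLod, , drop = FALSE]
  if (nrow(conf) == 0) conf <- r
  anchor <- conf[which.max(conf$theta), ]
  e1 <- anchor$marker_a; e2 <- anchor$marker_b
  thetaTo <- function(m, ref) {
    hit <- r[(r$marker_a == m & r$marker_b == ref) |
             (r$marker_b == m & r$marker_a == ref), "theta"]
    if (length(hit) == 0) NA_real_ else hit[1]
  }
  mid <- setdiff(members, c(e1, e2))
  t1 <- vapply(mid, thetaTo, numeric(1), ref = e1)
  t2 <- vapply(mid, thetaTo, numeric(1), ref = e2)
  ord <- c(e1, mid[order(t1, -t2, mid)], e2)
  thetaPrev <- c(NA_real_,
                 vapply(seq_along(ord)[-1], function(k)
                   thetaTo(ord[k], ord[k - 1]), numeric(1)))
  cmPrev <- rep(NA_real_, length(thetaPrev))
  okT <- !is.na(thetaPrev) & thetaPrev < 0.5
  cmPrev[okT] <- kosambiCm(thetaPrev[okT])
  data.frame(marker = ord, theta_prev = thetaPrev, cm_prev = cmPrev,
             cum_cm = cumsum(ifelse(is.na(cmPrev), 0, cmPrev)),
             stringsAsFactors = FALSE)
}

#' Write two-point results / a group map as TSV
#'
#' @param x `data.frame` ([twopointAll()] results or [orderGroup()] map).
#' @param file TSV path.
#' @return The path, invisibly.
#' @export
writeLinkageTable <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
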