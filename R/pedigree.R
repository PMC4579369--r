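# Pedigree algorithmics: recursive kinship / inbreeding with generation
# caps, founder-set ancestry, influential-ancestor ranking.

ped_env <- function(ped) {
  list(id = ped$id,
       sire = match(ped$sire, ped$id),
       dam = match(ped$dam, ped$id),
       rank = local({
         r <- integer(nrow(ped))
         ord <- attr(ped, "topo_order") %||% seq_len(nrow(ped))
         si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
         for (v in ord) {
           pr <- c(si[v], di[v]); pr <- pr[!is.na(pr)]
           r[v] <- if (length(pr)) 1L + max(r[pr]) else 0L
         }
         r
       }))
}

#' Kinship coefficient between two pedigree members
#'
#' The kinship coefficient f(a, b) is the probability that alleles drawn
#' at random, one from each individual, are identical by descent. It is
#' computed by the recursive tabular method: for x not an ancestor of y,
#' f(x, y) = (f(sire_x, y) + f(dam_x, y)) / 2, with unknown parents
#' contributing 0, and f(x, x) = (1 + f(sire_x, dam_x)) / 2. With a
#' finite generation cap `g`, any ancestor more than `g` generations above
#' the starting individuals (counted along each path) is treated as
#' unknown, reproducing fixed-depth pedigree software conventions.
#'
#' @param ped a [pedigree()].
#' @param a,b individual ids.
#' @param g generation cap (default `Inf` = full pedigree).
#' @return The kinship coefficient (numeric scalar in `[0, 1]`).
#' @seealso [coi()]
#' @export
kinship <- function(ped, a, b, g = Inf) {
  pe <- ped_env(ped)
  i <- match(a, pe$id); j <- match(b, pe$id)
  if (is.na(i)) stop("id not found: ", a)
  if (is.na(j)) stop("id not found: ", b)
  kin_rec(pe, i, 0L, j, 0L, g, new.env(parent = emptyenv()))
}

kin_rec <- function(pe, i, di, j, dj, g, memo) {
  if (is.na(i) || is.na(j)) return(0)
  # canonical memo key; depth matters only under a finite cap
  if (i > j || (i == j && di > dj)) {
    tmp <- i; i <- j; j <- tmp; tmp <- di; di <- dj; dj <- tmp
  }
  key <- if (is.finite(g)) paste(i, di, j, dj) else paste(i, j)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  val <- if (i == j) {
    if (di < g && dj < g)
      0.5 * (1 + kin_rec(pe, pe$sire[i], di + 1L, pe$dam[i], dj + 1L,
                         g, memo))
    else 0.5
  } else {
    # recurse on the individual deeper in the pedigree (later generation):
    # it cannot be an ancestor of the other
    if (pe$rank[i] >= pe$rank[j]) {
      if (di < g)
        0.5 * (kin_rec(pe, pe$sire[i], di + 1L, j, dj, g, memo) +
               kin_rec(pe, pe$dam[i], di + 1L, j, dj, g, memo))
      else 0
    } else {
      if (dj < g)
        0.5 * (kin_rec(pe, pe$sire[j], dj + 1L, i, di, g, memo) +
               kin_rec(pe, pe$dam[j], dj + 1L, i, di, g, memo))
      else 0
    }
  }
  memo[[key]] <- val
  val
}

#' Coefficient of inbreeding
#'
#' Wright's inbreeding coefficient F(x) - the probability that x's two
#' alleles at a locus are identical by descent - equals the kinship of
#' x's parents. With a finite cap `g`, ancestors more than `g` generations
#' above x are treated as unknown ("COI over g generations"); F computed
#' over deeper pedigrees is never smaller, since more ancestry can only
#' add common-ancestor paths.
#'
#' @param ped a [pedigree()].
#' @param x individual id (or vector of ids).
#' @param g generation cap counted above `x` (default `Inf`).
#' @return Numeric vector of inbreeding coefficients.
#' @export
coi <- function(ped, x, g = Inf) {
  pe <- ped_env(ped)
  idx <- match(x, pe$id)
  if (anyNA(idx)) stop("id not found: ", paste(x[is.na(idx)], collapse = ", "))
  memo <- new.env(parent = emptyenv())
  vapply(idx, function(i) {
    s <- pe$sire[i]; d <- pe$dam[i]
    if (is.na(s) || is.na(d)) 0
    else kin_rec(pe, s, 1L, d, 1L, g, if (is.finite(g))
      new.env(parent = emptyenv()) else memo)
  }, 0)
}

#' Expected genome fraction contributed by a founder set
#'
#' The ancestry coefficient of dog x to a named set of ancestors s (e.g.
#' the midcentury-bottleneck founders): c(x) = 1 if x is in s, 0 if x has
#' no known parents, otherwise the parental average
#' (c(sire) + c(dam)) / 2. The recursion stops at set members even when
#' their own parents are recorded, so descent routed through one set
#' member is not counted twice when members are related.
#'
#' @param ped a [pedigree()].
#' @param set character vector of ancestor ids (non-empty).
#' @param ids ids to evaluate (default: every pedigree member).
#' @return Data frame `id`, `coefficient` in `[0, 1]`.
#' @export
founder_contribution <- function(ped, set, ids = NULL) {
  if (!length(set)) stop("empty founder set")
  miss <- setdiff(set, ped$id)
  if (length(miss)) stop("set ids not in pedigree: ",
                         paste(miss, collapse = ", "))
  contrib <- contribution_vector(ped, set, severed = character(0))
  ids <- ids %||% ped$id
  idx <- match(ids, ped$id)
  if (anyNA(idx)) stop("id not found: ", paste(ids[is.na(idx)], collapse = ", "))
  data.frame(id = ids, coefficient = contrib[idx], row.names = NULL)
}

# Expected genome fraction from `set`, with `severed` individuals treated
# as founders (their parent links cut). Computed for all members in
# topological order.
contribution_vector <- function(ped, set, severed = character(0)) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  inset <- ped$id %in% set
  cut <- ped$id %in% severed & !inset
  contrib <- numeric(n)
  ord <- attr(ped, "topo_order") %||% seq_len(n)
  for (v in ord) {
    if (inset[v]) { contrib[v] <- 1; next }
    if (cut[v]) { contrib[v] <- 0; next }
    s <- si[v]; d <- di[v]
    if (is.na(s) && is.na(d)) { contrib[v] <- 0; next }
    contrib[v] <- 0.5 * ((if (is.na(s)) 0 else contrib[s]) +
                         (if (is.na(d)) 0 else contrib[d]))
  }
  contrib
}

strict_ancestors <- function(ped, ids) {
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  seen <- logical(nrow(ped))
  queue <- match(ids, ped$id)
  queue <- unique(c(si[queue], di[queue]))
  queue <- queue[!is.na(queue)]
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    if (seen[v]) next
    seen[v] <- TRUE
    for (p in c(si[v], di[v])) if (!is.na(p) && !seen[p])
      queue <- c(queue, p)
  }
  ped$id[seen]
}

#' Rank the most influential ancestors of a reference population
#'
#' Greedy probability-of-gene-origin ranking: the first ancestor selected
#' maximizes the mean expected genome contribution to the reference dogs;
#' each later ancestor maximizes its *marginal* contribution, computed on
#' a pedigree in which the already-selected ancestors' parent links are
#' severed so genome already attributed to them cannot be counted again.
#' Marginals are therefore non-negative and their cumulative sum cannot
#' exceed 1. Ties are broken by earliest birth date, then id.
#'
#' @param ped a [pedigree()].
#' @param ref character vector of reference ids (non-empty).
#' @param k number of ancestors to rank (truncated to the number of
#'   distinct ancestors).
#' @return Data frame `rank`, `id`, `raw` (unconditional mean
#'   contribution), `marginal` (contribution at selection time).
#' @export
influential_ancestors <- function(ped, ref, k = 10) {
  if (!length(ref)) stop("empty reference population")
  cand <- strict_ancestors(ped, ref)
  if (!length(cand)) return(data.frame(rank = integer(0), id = character(0),
                                       raw = numeric(0), marginal = numeric(0)))
  k <- min(k, length(cand))
  ref_idx <- match(ref, ped$id)
  mean_contrib <- function(a, severed)
    mean(contribution_vector(ped, a, severed)[ref_idx])
  raw <- vapply(cand, mean_contrib, 0, severed = character(0))
  dob <- ped$dob[match(cand, ped$id)]
  sel <- character(0); marg <- numeric(0)
  remaining <- cand
  for (r in seq_len(k)) {
    m <- vapply(remaining, mean_contrib, 0, severed = sel)
    best <- max(m)
    top <- remaining[m >= best - 1e-12]
    if (length(top) > 1L) {
      d <- ped$dob[match(top, ped$id)]
      ord <- order(!is.na(d), d, top, decreasing = c(TRUE, FALSE, FALSE),
                   method = "radix")
      top <- top[ord]
    }
    pickid <- top[1L]
    sel <- c(sel, pickid)
    marg <- c(marg, m[match(pickid, remaining)])
    remaining <- setdiff(remaining, pickid)
    if (!length(remaining)) break
  }
  data.frame(rank = seq_along(sel), id = sel,
             raw = raw[match(sel, cand)], marginal = marg,
             row.names = NULL)
}

#' Ancestry-versus-disease ratio curve
#'
#' Bins dogs by their ancestry coefficient to a target ancestor (or set)
#' and reports the ratio of affected to healthy dogs per bin - the
#' tipping-point display used to relate a single ancestor's genetic
#' contribution to disease incidence.
#'
#' @param ped a [pedigree()].
#' @param target ancestor id or character vector (a founder set).
#' @param affected,healthy disjoint character vectors of ids.
#' @param bin_width bin width on the ancestry coefficient (> 0).
#' @return Data frame `bin_low`, `bin_high` (half-open bins), `affected`,
#'   `healthy`, `ratio` (NA where no healthy dog falls in the bin).
#' @export
ancestry_disease_curve <- function(ped, target, affected, healthy,
                                   bin_width = 0.01) {
  if (bin_width <= 0) stop("bin width must be positive")
  if (length(intersect(affected, healthy)))
    stop("affected and healthy overlap")
  cv <- founder_contribution(ped, target, ids = c(affected, healthy))
  grp <- rep(c("affected", "healthy"), c(length(affected), length(healthy)))
  bin <- floor(cv$coefficient / bin_width)
  maxbin <- max(bin)
  bins <- 0:maxbin
  aff <- tabulate(bin[grp == "affected"] + 1L, nbins = maxbin + 1L)
  hea <- tabulate(bin[grp == "healthy"] + 1L, nbins = maxbin + 1L)
  data.frame(bin_low = bins * bin_width,
             bin_high = (bins + 1) * bin_width,
             affected = aff, healthy = hea,
             ratio = ifelse(hea > 0, aff / hea, NA_real_))
}

#' Per-decade ancestry and inbreeding summary
#'
#' Groups dogs by birth decade (floor(year / 10) x 10) and reports, per
#' decade and cohort, the mean ancestry percentage for each named founder
#' set and the mean inbreeding coefficient at each generation cap. Dogs
#' without a birth date are excluded from decade rows and counted in the
#' `n_undated` attribute.
#'
#' @param ped a [pedigree()] with birth dates.
#' @param sets named list of founder sets (character vectors), e.g.
#'   a subset of [founder_sets()] resolved to pedigree ids.
#' @param g_list generation caps for the mean COI columns (default
#'   `c(10, 15)`).
#' @param by_cohort also emit per-cohort rows using the pedigree's
#'   `cohort` column (a `total` row is always emitted).
#' @return Data frame with `decade`, `cohort`, `n`, one `pct_<set>` column
#'   per set and one `coi_<g>` column per cap.
#' @export
decade_summary <- function(ped, sets, g_list = c(10, 15),
                           by_cohort = TRUE) {
  dated <- !is.na(ped$dob)
  if (!any(dated)) return(data.frame())
  decade <- rep(NA_integer_, nrow(ped))
  decade[dated] <- (as.integer(format(ped$dob[dated], "%Y")) %/% 10L) * 10L
  contrib <- lapply(sets, function(s)
    contribution_vector(ped, s))
  cois <- lapply(g_list, function(g) coi(ped, ped$id, g = g))
  one_row <- function(rows, dec, coh) {
    out <- data.frame(decade = dec, cohort = coh, n = length(rows))
    for (nm in names(sets))
      out[[paste0("pct_", nm)]] <- 100 * mean(contrib[[nm]][rows])
    for (i in seq_along(g_list))
      out[[paste0("coi_", g_list[i])]] <- 100 * mean(cois[[i]][rows])
    out
  }
  res <- list()
  for (dec in sort(unique(decade[dated]))) {
    rows <- which(decade == dec)
    res[[length(res) + 1L]] <- one_row(rows, dec, "total")
    if (by_cohort) {
      for (coh in sort(unique(ped$cohort[rows]))) {
        if (is.na(coh) || coh %in% c("total", "")) next
        res[[length(res) + 1L]] <-
          one_row(rows[ped$cohort[rows] %in% coh], dec, coh)
      }
    }
  }
  out <- do.call(rbind, res)
  attr(out, "n_undated") <- sum(!dated)
  out
}
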