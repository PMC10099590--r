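#' Read and validate a pedigree file
#'
#' Reads a CSV pedigree (columns \code{id,sire,dam,birth_date,sex,flock}),
#' normalises unknown-parent codes ("0", "", NA) to \code{NA}, checks for
#' duplicate ids and cycles, and returns the rows topologically sorted so that
#' parents always precede their offspring.
#'
#' @param path Path to a UTF-8 CSV file with a header. Columns \code{id},
#'   \code{sire} and \code{dam} are required; \code{birth_date} (ISO-8601),
#'   \code{sex} (\code{M}/\code{F}) and \code{flock} are optional.
#' @param date_order_error If \code{TRUE}, a parent born after its offspring is
#'   an error; by default it is a warning.
#' @return A \code{data.frame} of class \code{"pedigree"} with columns
#'   \code{id}, \code{sire}, \code{dam}, \code{birth_date}, \code{sex},
#'   \code{flock}, sorted parents-before-offspring.
#' @export
read_pedigree <- function(path, date_order_error = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  names(raw) <- tolower(names(raw))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(raw)))
    stop("pedigree file must have columns id, sire, dam; found: ",
         paste(names(raw), collapse = ", "))
  ped <- data.frame(
    id   = trimws(raw$id),
    sire = trimws(raw$sire),
    dam  = trimws(raw$dam),
    stringsAsFactors = FALSE
  )
  ped$birth_date <- if ("birth_date" %in% names(raw))
    as.Date(raw$birth_date) else as.Date(rep(NA, nrow(ped)))
  ped$sex   <- if ("sex" %in% names(raw)) toupper(trimws(raw$sex)) else NA_character_
  ped$flock <- if ("flock" %in% names(raw)) trimws(raw$flock) else NA_character_
  as_pedigree(ped, date_order_error = date_order_error)
}

#' Construct a validated pedigree from a data frame
#'
#' @param ped Data frame with at least \code{id}, \code{sire}, \code{dam}.
#' @inheritParams read_pedigree
#' @return A sorted \code{"pedigree"} data frame; see [read_pedigree()].
#' @export
as_pedigree <- function(ped, date_order_error = FALSE) {
  ped <- as.data.frame(ped, stringsAsFactors = FALSE)
  for (col in c("id", "sire", "dam")) {
    ped[[col]] <- as.character(ped[[col]])
    ped[[col]][ped[[col]] %in% c("0", "", "NA")] <- NA_character_
  }
  if (anyNA(ped$id)) stop("missing animal id in pedigree")
  if (anyDuplicated(ped$id))
    stop("duplicate animal_id in pedigree: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  if (!"birth_date" %in% names(ped)) ped$birth_date <- as.Date(rep(NA, nrow(ped)))
  if (!"sex" %in% names(ped)) ped$sex <- NA_character_
  if (!"flock" %in% names(ped)) ped$flock <- NA_character_

  # parents that never appear as animals become founders of record
  known <- ped$id
  orphan_parents <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), known)
  if (length(orphan_parents)) {
    add <- data.frame(id = orphan_parents, sire = NA_character_,
                      dam = NA_character_,
                      birth_date = as.Date(rep(NA, length(orphan_parents))),
                      sex = NA_character_, flock = NA_character_,
                      stringsAsFactors = FALSE)
    ped <- rbind(ped[, names(add)], add)
  }

  ord <- pedigree_toposort(ped$id, ped$sire, ped$dam)
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL

  # date sanity: offspring must not be older than a known parent
  if (!all(is.na(ped$birth_date))) {
    bd <- ped$birth_date
    names(bd) <- ped$id
    for (p in c("sire", "dam")) {
      has <- !is.na(ped[[p]]) & !is.na(bd[ped[[p]]]) & !is.na(ped$birth_date)
      bad <- has & ped$birth_date < bd[ped[[p]]]
      if (any(bad)) {
        msg <- paste0("parent born after offspring for: ",
                      paste(utils::head(ped$id[bad], 5), collapse = ", "))
        if (date_order_error) stop(msg) else warning(msg)
      }
    }
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn's algorithm; errors with one individual on a cycle if any.
pedigree_toposort <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam),  0L, idx[dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) if (p > 0L) {
      indeg[i] <- indeg[i] + 1L
      children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    # stable: keep original file order among ready nodes
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    on_cycle <- setdiff(idx, out)
    stop("pedigree contains a cycle involving individual '",
         id[on_cycle[1L]], "'")
  }
  out
}

# integer-coded parents (0 = unknown) for a sorted pedigree
ped_codes <- function(ped) {
  idx <- seq_len(nrow(ped)); names(idx) <- ped$id
  list(
    s = ifelse(is.na(ped$sire), 0L, idx[ped$sire]),
    d = ifelse(is.na(ped$dam),  0L, idx[ped$dam]),
    ids = ped$id
  )
}

#' Numerator relationship matrix by the tabular method
#'
#' Builds the full additive relationship matrix A by the recursive tabular
#' method (A_ii = 1 + 0.5 A_sd; A_ij = 0.5 (A_j,sire + A_j,dam)), with unknown
#' parents treated as unrelated, non-inbred base animals.
#'
#' @param ped A sorted \code{"pedigree"} (see [as_pedigree()]).
#' @param subset Optional vector of ids: the full A is computed and then the
#'   principal submatrix on these ids is returned (this is A22 when
#'   \code{subset} is the genotyped cohort, not the NRM of the sub-pedigree).
#' @return A symmetric numeric matrix with ids as dimnames.
#' @export
build_nrm <- function(ped, subset = NULL) {
  pc <- ped_codes(ped)
  n <- length(pc$ids)
  A <- matrix(0, n, n, dimnames = list(pc$ids, pc$ids))
  for (i in seq_len(n)) {
    s <- pc$s[i]; d <- pc$d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + 0.5 * A[s, j]
      if (d > 0L) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  if (!is.null(subset)) {
    subset <- as.character(subset)
    missing <- setdiff(subset, pc$ids)
    if (length(missing))
      stop("subset ids not in pedigree: ", paste(missing, collapse = ", "))
    A <- A[subset, subset, drop = FALSE]
  }
  A
}

#' Inbreeding coefficients without the full relationship matrix
#'
#' Computes f_i = A_ii - 1 for every animal by the Meuwissen-Luo recursion
#' (one sparse L-row per animal), so no dense A is formed. Animals with any
#' unknown parent have f = 0 under the unrelated-base assumption.
#'
#' @param ped A sorted \code{"pedigree"}.
#' @return Named numeric vector of inbreeding coefficients, in pedigree order.
#' @export
inbreeding <- function(ped) {
  pc <- ped_codes(ped)
  s <- pc$s; d <- pc$d
  n <- length(s)
  f <- numeric(n)
  Dv <- numeric(n)  # Mendelian sampling variances, filled in order
  L <- numeric(n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    Dv[i] <- if (si > 0L && di > 0L) 0.5 - 0.25 * (f[si] + f[di])
             else if (si > 0L) 0.75 - 0.25 * f[si]
             else if (di > 0L) 0.75 - 0.25 * f[di]
             else 1
    if (si == 0L || di == 0L) { f[i] <- 0; next }
    if (i > 1L && si == s[i - 1L] && di == d[i - 1L]) { f[i] <- f[i - 1L]; next }
    # accumulate row i of L over ancestors, descending index
    L[seq_len(i)] <- 0
    L[i] <- 1
    fi <- -1
    for (j in i:1L) {
      lj <- L[j]
      if (lj == 0) next
      fi <- fi + lj * lj * Dv[j]
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * lj
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * lj
    }
    f[i] <- fi
  }
  names(f) <- pc$ids
  f
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes 1/d_i to its
#' diagonal, -1/(2 d_i) to animal-parent cells and 1/(4 d_i) among known
#' parents, where d_i = 0.5 - 0.25 (f_s + f_d) (0.75 - 0.25 f_p with one
#' known parent, 1 with none).
#'
#' @param ped A sorted \code{"pedigree"}.
#' @param f Optional precomputed inbreeding vector (pedigree order).
#' @return A sparse symmetric \code{Matrix::dsCMatrix} with ids as dimnames.
#' @export
nrm_inverse <- function(ped, f = NULL) {
  pc <- ped_codes(ped)
  s <- pc$s; d <- pc$d
  n <- length(s)
  if (is.null(f)) f <- inbreeding(ped)
  fpad <- c(0, unname(f))  # index parent+1, unknown -> f = 0 contribution path
  di <- ifelse(s > 0L & d > 0L, 0.5 - 0.25 * (fpad[s + 1L] + fpad[d + 1L]),
        ifelse(s > 0L, 0.75 - 0.25 * fpad[s + 1L],
        ifelse(d > 0L, 0.75 - 0.25 * fpad[d + 1L], 1)))
  b <- 1 / di
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  # vectorised contribution lists
  i_all <- seq_len(n)
  add(i_all, i_all, b)
  for (p in list(s, d)) {
    k <- p > 0L
    add(i_all[k], p[k], -0.5 * b[k])
    add(p[k], i_all[k], -0.5 * b[k])
  }
  k <- s > 0L & d > 0L
  add(s[k], d[k], 0.25 * b[k])
  add(d[k], s[k], 0.25 * b[k])
  k2 <- s > 0L
  add(s[k2], s[k2], 0.25 * b[k2])
  k2 <- d > 0L
  add(d[k2], d[k2], 0.25 * b[k2])
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(pc$ids, pc$ids))
  Matrix::forceSymmetric(Ainv)
}

#' Pedigree relationships among genotyped animals and their inverse
#'
#' Extracts A22, the principal submatrix of the full A restricted to a
#' genotyped cohort, together with its dense inverse.
#'
#' @param ped A sorted \code{"pedigree"}.
#' @param genotyped_ids Character vector of genotyped animal ids.
#' @return List with elements \code{a22} and \code{a22_inv} (dense symmetric
#'   matrices, ids as dimnames).
#' @export
extract_a22 <- function(ped, genotyped_ids) {
  a22 <- build_nrm(ped, subset = genotyped_ids)
  a22_inv <- tryCatch(solve(a22), error = function(e)
    stop("A22 is singular (duplicate or identical animals?); ",
         "remove duplicates or jitter the cohort: ", conditionMessage(e)))
  dimnames(a22_inv) <- dimnames(a22)
  list(a22 = a22, a22_inv = a22_inv)
}

#' Pedigree completeness index
#'
#' MacCluer-style completeness: for each parental line,
#' C = (1/d) * sum over generations g of (known ancestors at g) / 2^g, and the
#' index is the harmonic mean 2 Cs Cd / (Cs + Cd) (0 when either line is 0).
#'
#' @param ped A sorted \code{"pedigree"}.
#' @param depth_d Number of ancestral generations considered (default 5).
#' @param cohort Optional ids over which the mean/SD summary is computed
#'   (default: all animals).
#' @return List with \code{pci} (named vector), \code{depth_d}, \code{mean},
#'   \code{sd} over the cohort.
#' @export
pedigree_completeness <- function(ped, depth_d = 5, cohort = NULL) {
  stopifnot(depth_d >= 1)
  pc <- ped_codes(ped)
  s <- pc$s; d <- pc$d
  n <- length(s)
  # anc[i, g]: number of known ancestors of i at generation g (g = 1: parents)
  anc <- matrix(0, n, depth_d)
  anc[, 1] <- (s > 0L) + (d > 0L)
  if (depth_d > 1) {
    for (g in 2:depth_d) {
      prev <- anc[, g - 1L]
      kg <- numeric(n)
      ks <- s > 0L; kd <- d > 0L
      kg[ks] <- kg[ks] + prev[s[ks]]
      kg[kd] <- kg[kd] + prev[d[kd]]
      anc[, g] <- kg
    }
  }
  # per-line completeness: C_line(i) = (1/d) sum_g known_in_line(i, g) / 2^(g-1)
  # line through sire = {sire} union ancestors of sire shifted one generation
  line_c <- function(parent) {
    Cl <- numeric(n)
    w <- 2^(seq_len(depth_d) - 1L)  # expected ancestors within one line at g
    for (i in seq_len(n)) {
      p <- parent[i]
      if (p == 0L) next
      cnt <- c(1, if (depth_d > 1) anc[p, seq_len(depth_d - 1L)] else NULL)
      Cl[i] <- sum(cnt / w) / depth_d
    }
    Cl
  }
  cs <- line_c(s)
  cd <- line_c(d)
  pci <- ifelse(cs == 0 | cd == 0, 0, 2 * cs * cd / (cs + cd))
  names(pci) <- pc$ids
  coh <- if (is.null(cohort)) pc$ids else as.character(cohort)
  list(pci = pci, depth_d = depth_d,
       mean = mean(pci[coh]), sd = stats::sd(pci[coh]))
}

#' Export a relationship matrix as sparse triplet text
#'
#' Writes the lower triangle (including diagonal) as tab-separated
#' \code{row_id, col_id, value}.
#'
#' @param m Symmetric matrix (dense or sparse) with id dimnames.
#' @param path Output file path.
#' @param zero_tol Entries with |value| below this are omitted.
#' @export
write_relmat <- function(m, path, zero_tol = 0) {
  m <- as.matrix(m)
  ids <- rownames(m)
  lt <- which(lower.tri(m, diag = TRUE), arr.ind = TRUE)
  val <- m[lt]
  keep <- abs(val) > zero_tol
  out <- data.frame(row_id = ids[lt[keep, 1]], col_id = ids[lt[keep, 2]],
                    value = val[keep])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
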