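#' Kinship matrix from a pedigree
#'
#' Computes pairwise kinship coefficients by the classical recursion:
#' founders are unrelated with self-kinship 1/2;
#' `phi(i,i) = (1 + phi(father_i, mother_i)) / 2`; and for j not a
#' descendant of i, `phi(i,j) = (phi(father_i, j) + phi(mother_i, j)) / 2`.
#' Individuals are processed in topological order (parents before
#' offspring), which the function derives itself; a cycle or an unknown
#' parent id is an error.
#'
#' @param pedigree `data.frame` with columns `individual_id`, `father_id`,
#'   `mother_id` (NA or "0" for founders).
#' @return Symmetric kinship matrix with individual ids as dimnames.
#'   Multiply by 2 for the expected-relatedness matrix used as the
#'   polygenic covariance.
#' @examples
#' ped <- data.frame(individual_id = c("f", "m", "s1", "s2"),
#'                   father_id = c(NA, NA, "f", "f"),
#'                   mother_id = c(NA, NA, "m", "m"))
#' kinship_from_pedigree(ped)["s1", "s2"]  # 0.25
#' @export
kinship_from_pedigree <- function(pedigree) {
  ids <- pedigree$individual_id
  if (anyDuplicated(ids)) stop("duplicate individual ids in pedigree")
  fa <- pedigree$father_id
  mo <- pedigree$mother_id
  fa[fa %in% c("0", "")] <- NA
  mo[mo %in% c("0", "")] <- NA
  known <- c(fa[!is.na(fa)], mo[!is.na(mo)])
  if (!all(known %in% ids))
    stop("unknown parent id(s): ",
         paste(unique(setdiff(known, ids)), collapse = ", "))
  n <- length(ids)
  fi <- match(fa, ids)
  mi <- match(mo, ids)

  ## Kahn topological sort: founders first
  placed <- logical(n)
  order_idx <- integer(0)
  repeat {
    ready <- which(!placed &
                   (is.na(fi) | placed[pmax(fi, 1L)] | is.na(fi)) &
                   (is.na(mi) | placed[pmax(mi, 1L)] | is.na(mi)))
    ready <- ready[vapply(ready, function(i) {
      (is.na(fi[i]) || placed[fi[i]]) && (is.na(mi[i]) || placed[mi[i]])
    }, logical(1))]
    if (length(ready) == 0) break
    placed[ready] <- TRUE
    order_idx <- c(order_idx, ready)
  }
  if (length(order_idx) < n)
    stop("pedigree contains a cycle involving: ",
         paste(ids[!placed], collapse = ", "))

  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  done <- integer(0)
  for (i in order_idx) {
    f <- fi[i]; m <- mi[i]
    phi[i, i] <- 0.5 * (1 + if (!is.na(f) && !is.na(m)) phi[f, m] else 0)
    if (length(done)) {
      pf <- if (!is.na(f)) phi[f, done] else rep(0, length(done))
      pm <- if (!is.na(m)) phi[m, done] else rep(0, length(done))
      phi[i, done] <- 0.5 * (pf + pm)
      phi[done, i] <- phi[i, done]
    }
    done <- c(done, i)
  }
  phi
}
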