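# BeePop: an ordered collection of individuals of one role.
#
# Column-oriented fields (id, parents, ploidy) plus per-individual genomes:
# haplo[[i]] is a list with one ploidy x nSites 0/1 matrix per chromosome,
# ibd[[i]] the matching founder-haplotype origin labels. Caste is not stored
# here: it lives in the global registry (castes can change at mating).

#' @noRd
newBeePop <- function(id = character(0), mother = rep(NA_character_, length(id)),
                      father = rep(NA_character_, length(id)),
                      ploidy = rep(2L, length(id)),
                      haplo = vector("list", length(id)),
                      ibd = vector("list", length(id)),
                      misc = rep(list(list()), length(id)),
                      pheno = NULL) {
  structure(
    list(id = as.character(id), mother = as.character(mother),
         father = as.character(father), ploidy = as.integer(ploidy),
         haplo = haplo, ibd = ibd, misc = misc, pheno = pheno),
    class = "BeePop"
  )
}

#' Number of individuals in a population
#'
#' @param pop a `BeePop` object.
#' @return Integer count.
#' @export
nInd <- function(pop) {
  stopifnot(inherits(pop, "BeePop"))
  length(pop$id)
}

#' @export
`[.BeePop` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$id)
  if (anyNA(i)) stopf("unknown individual id in subset")
  newBeePop(x$id[i], x$mother[i], x$father[i], x$ploidy[i],
            x$haplo[i], x$ibd[i], x$misc[i],
            if (!is.null(x$pheno)) x$pheno[i, , drop = FALSE])
}

#' @export
c.BeePop <- function(...) {
  pops <- list(...)
  pops <- pops[!vapply(pops, is.null, TRUE)]
  stopifnot(all(vapply(pops, inherits, TRUE, "BeePop")))
  ids <- unlist(lapply(pops, `[[`, "id"))
  if (anyDuplicated(ids)) stopf("cannot combine populations with duplicated ids")
  phenos <- lapply(pops, `[[`, "pheno")
  pheno <- if (all(!vapply(phenos, is.null, TRUE)) && length(phenos)) {
    do.call(rbind, phenos)
  } else NULL
  newBeePop(ids,
            unlist(lapply(pops, `[[`, "mother")),
            unlist(lapply(pops, `[[`, "father")),
            unlist(lapply(pops, `[[`, "ploidy")),
            do.call(c, lapply(pops, `[[`, "haplo")),
            do.call(c, lapply(pops, `[[`, "ibd")),
            do.call(c, lapply(pops, `[[`, "misc")),
            pheno)
}

#' @exportS3Method base::print
print.BeePop <- function(x, ...) {
  cat(sprintf("BeePop with %d individual(s)\n", nInd(x)))
  if (nInd(x)) {
    n <- min(nInd(x), 6L)
    df <- data.frame(id = x$id[seq_len(n)], mother = x$mother[seq_len(n)],
                     father = x$father[seq_len(n)], ploidy = x$ploidy[seq_len(n)])
    print(df, row.names = FALSE)
    if (nInd(x) > n) cat("  ...\n")
  }
  invisible(x)
}
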