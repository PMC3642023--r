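#' Pedigree construction and PED input
#'
#' famprior handles a single two-founder nuclear family: two parents and one
#' generation of children, with a binary affected status. The affected,
#' sequenced children are the probands.
#'
#' @param id,father,mother character vectors; `NA` or `"0"` marks a missing
#'   (founder) parent.
#' @param sex integer 1 = male, 2 = female, 0 = unknown.
#' @param affected logical.
#' @return data.frame of class `pedigree` with columns `id`, `father`,
#'   `mother`, `sex`, `affected`, `founder`.
#' @export
pedigree <- function(id, father, mother, sex, affected) {
  id <- as.character(id); father <- as.character(father); mother <- as.character(mother)
  father[father %in% "0"] <- NA; mother[mother %in% "0"] <- NA
  if (anyDuplicated(id)) stop("duplicate member id in pedigree: ", id[duplicated(id)][1])
  founder <- is.na(father) & is.na(mother)
  if (any(is.na(father) != is.na(mother)))
    stop("members must have either both parents or neither")
  known <- c(father, mother); known <- known[!is.na(known)]
  if (!all(known %in% id))
    stop("parent id not a pedigree member: ", setdiff(known, id)[1])
  ped <- data.frame(id = id, father = father, mother = mother,
                    sex = as.integer(sex), affected = as.logical(affected),
                    founder = founder, stringsAsFactors = FALSE)
  if (sum(founder) != 2L)
    stop("expected exactly two founders (a nuclear family), got ", sum(founder))
  kids <- ped[!founder, ]
  if (length(unique(kids$father)) != 1L || length(unique(kids$mother)) != 1L)
    stop("all children must share the same two parents")
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' @rdname pedigree
#' @param ped a `pedigree`.
#' @export
ped_children <- function(ped) ped$id[!ped$founder]

#' @rdname pedigree
#' @export
ped_probands <- function(ped) ped$id[!ped$founder & ped$affected]

#' @rdname pedigree
#' @export
ped_father <- function(ped) {
  unique(ped$father[!ped$founder])
}

#' @rdname pedigree
#' @export
ped_mother <- function(ped) {
  unique(ped$mother[!ped$founder])
}

#' Read a 6-column PED file
#'
#' Columns: family, id, father, mother, sex, phenotype; `0` marks a missing
#' parent; phenotype 2 = affected, 1 = unaffected.
#'
#' @param path PED file path.
#' @return a [pedigree()].
#' @export
read_ped <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(raw) < 6L) stop("PED file must have 6 columns: ", path)
  if (length(unique(raw[[1]])) != 1L)
    stop("PED file contains more than one family: ", path)
  pedigree(id = raw[[2]], father = raw[[3]], mother = raw[[4]],
           sex = as.integer(raw[[5]]), affected = raw[[6]] == "2")
}

#' Write a pedigree as a 6-column PED file
#'
#' @param ped a `pedigree`.
#' @param path output file.
#' @param family family id for column 1.
#' @export
write_ped <- function(ped, path, family = "FAM1") {
  out <- data.frame(family, ped$id,
                    ifelse(is.na(ped$father), "0", ped$father),
                    ifelse(is.na(ped$mother), "0", ped$mother),
                    ped$sex, ifelse(ped$affected, 2L, 1L))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
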