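# Sequence similarity, UPGMA tree and cluster extraction (HOH step 1).
#
# Newick serialization is done in-package: HLA allele names contain '*'
# and ':', which are reserved in Newick, so labels are single-quoted and
# the writer/parser pair keeps them intact.

#' Pairwise allele distances on aligned residues
#'
#' Distance between two alleles is the proportion of differing residues
#' among positions non-missing in both (normalized Hamming distance).
#' By default only mature-chain positions (beta >= 1) enter; the signal
#' peptide (-29..-1) is excluded.
#'
#' @param catalog An \code{allele_catalog}.
#' @param positions Optional integer vector of positions to use; default
#'   all mature-chain positions present in the catalog.
#' @param include_signal_peptide If \code{TRUE} and \code{positions} is
#'   \code{NULL}, signal-peptide columns are kept.
#' @return Object of class \code{dist_matrix}: list with \code{labels}
#'   and symmetric matrix \code{d} (zero diagonal, values in [0, 1]).
#' @export
pairwise_distances <- function(catalog, positions = NULL,
                               include_signal_peptide = FALSE) {
  if (nrow(catalog$seq) < 2L) stop("need at least 2 alleles", call. = FALSE)
  if (is.null(positions)) {
    keep <- if (include_signal_peptide) seq_along(catalog$positions)
            else which(catalog$positions >= 1L)
  } else {
    keep <- match(as.integer(positions), catalog$positions)
    if (anyNA(keep)) stop("position(s) not in catalog", call. = FALSE)
  }
  mat <- catalog$seq[, keep, drop = FALSE]
  n <- nrow(mat)
  labs <- rownames(mat)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(mat[i, ]) & !is.na(mat[j, ])
      if (!any(ok)) {
        stop("alleles ", labs[i], " and ", labs[j],
             " share no non-missing positions", call. = FALSE)
      }
      d[i, j] <- d[j, i] <- mean(mat[i, ok] != mat[j, ok])
    }
  }
  structure(list(labels = labs, d = d), class = "dist_matrix")
}

#' Write a labelled square distance matrix as TSV
#' @param dm A \code{dist_matrix}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_distance_tsv <- function(dm, path) {
  df <- data.frame(allele = dm$labels, dm$d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the allele hierarchy by UPGMA
#'
#' Average-linkage (UPGMA) agglomeration over a distance matrix.  Merges
#' are deterministic: among candidate pairs at the minimal distance the
#' pair whose smallest member name sorts first (then the partner's
#' smallest name) is merged.  Merge heights are the between-cluster
#' average distances, so the resulting tree is ultrametric with
#' leaf-to-root path length equal to half the merge distance.
#'
#' @param dm A \code{dist_matrix}.
#' @return Object of class \code{similarity_tree}: list with an
#'   \code{hclust}-style component (\code{merge}, \code{height},
#'   \code{labels}), the per-merge member sets, and the leaf
#'   \code{labels}.
#' @export
build_tree <- function(dm) {
  d <- dm$d
  labs <- dm$labels
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  n <- length(labs)
  if (n < 2L) stop("need at least 2 leaves", call. = FALSE)

  # active cluster bookkeeping: id < 0 => leaf -id, id > 0 => merge row
  active <- data.frame(id = -seq_len(n), size = 1L, minlab = labs,
                       stringsAsFactors = FALSE)
  cur <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))       # leaf indices per active cluster
  step_members <- vector("list", n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- nrow(active)
    dm_min <- Inf; best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        dij <- cur[i, j]
        pick <- FALSE
        if (dij < dm_min - 1e-15) {
          pick <- TRUE
        } else if (abs(dij - dm_min) <= 1e-15 && !is.null(best)) {
          key_new <- sort(c(active$minlab[i], active$minlab[j]))
          key_old <- sort(c(active$minlab[best[1]], active$minlab[best[2]]))
          if (key_new[1] < key_old[1] ||
              (key_new[1] == key_old[1] && key_new[2] < key_old[2])) {
            pick <- TRUE
          }
        }
        if (pick) { dm_min <- min(dm_min, dij); best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(active$id[i], active$id[j]))
    height[step] <- dm_min
    ni <- active$size[i]; nj <- active$size[j]
    # UPGMA average-linkage update
    newrow <- (ni * cur[i, ] + nj * cur[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(m), c(i, j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], newrow[keep]),
                 c(newrow[keep], 0))
    merged <- c(members[[i]], members[[j]])
    step_members[[step]] <- sort(merged)
    members <- c(members[keep], list(merged))
    active <- rbind(active[keep, , drop = FALSE],
                    data.frame(id = step, size = ni + nj,
                               minlab = min(active$minlab[c(i, j)]),
                               stringsAsFactors = FALSE))
  }

  hc <- structure(list(merge = merge, height = height, labels = labs,
                       method = "average", dist.method = "hamming"),
                  class = "hclust")
  structure(list(hclust = hc, members = step_members, labels = labs),
            class = "similarity_tree")
}

#' @export
print.similarity_tree <- function(x, ...) {
  cat("<similarity_tree>", length(x$labels), "leaves, root height",
      format(max(x$hclust$height) / 2, digits = 4), "\n")
  invisible(x)
}

#' Extract the smallest cluster (clade) containing all seed alleles
#'
#' @param tree A \code{similarity_tree}.
#' @param seed_alleles Character vector of leaf names.
#' @param label Optional cluster label (e.g. \code{"DR4"}).
#' @return Object of class \code{allele_cluster}: list with \code{label}
#'   and \code{members} (character vector).
#' @export
extract_cluster <- function(tree, seed_alleles, label = NULL) {
  seed_alleles <- unique(seed_alleles)
  idx <- match(seed_alleles, tree$labels)
  if (anyNA(idx)) {
    stop("seed(s) not a leaf: ",
         paste(seed_alleles[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  members <- if (length(idx) == 1L) {
    tree$labels[idx]
  } else {
    # merges are recorded smallest-first, so the first step whose member
    # set covers the seeds is the smallest containing clade
    hit <- NULL
    for (k in seq_along(tree$members)) {
      if (all(idx %in% tree$members[[k]])) { hit <- k; break }
    }
    tree$labels[tree$members[[hit]]]
  }
  structure(list(label = label %||% "cluster", members = members),
            class = "allele_cluster")
}

#' @export
print.allele_cluster <- function(x, ...) {
  cat("<allele_cluster>", x$label, "-", length(x$members), "alleles\n")
  invisible(x)
}

# --- Newick serialization ----------------------------------------------

nwk_quote <- function(label) {
  if (grepl("[][ ,:;()']", label)) {
    paste0("'", gsub("'", "''", label), "'")
  } else label
}

nwk_fmt <- function(x) sprintf("%.12g", x)

# recursive serialization of a similarity_tree node (id convention as in
# hclust merge rows); child order: smallest member label first
nwk_serialize <- function(tree, id, parent_h) {
  hc <- tree$hclust
  if (id < 0) {
    lab <- tree$labels[-id]
    return(paste0(nwk_quote(lab), ":", nwk_fmt(parent_h)))
  }
  h <- hc$height[id] / 2
  kids <- hc$merge[id, ]
  minlab <- vapply(kids, function(k) {
    if (k < 0) tree$labels[-k] else tree$labels[min(tree$members[[k]])]
  }, character(1))
  kids <- kids[order(minlab)]
  inner <- paste(vapply(kids, function(k) nwk_serialize(tree, k, h - if (k < 0) 0 else hc$height[k] / 2),
                        character(1)), collapse = ",")
  if (is.na(parent_h)) paste0("(", inner, ")")
  else paste0("(", inner, "):", nwk_fmt(parent_h))
}

#' Write a tree in Newick format
#'
#' Branch lengths are height differences on the ultrametric (height/2)
#' scale.  Labels containing Newick-reserved characters (as all HLA
#' allele names do) are single-quoted.  Children of every node are
#' ordered by their smallest leaf label, so output is canonical and a
#' write-parse-write round trip is idempotent.
#'
#' @param tree A \code{similarity_tree} or a parsed \code{newick_tree}
#'   (from \code{\link{read_newick}}).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_newick <- function(tree, path) {
  txt <- if (inherits(tree, "similarity_tree")) {
    paste0(nwk_serialize(tree, nrow(tree$hclust$merge), NA_real_), ";")
  } else if (inherits(tree, "newick_tree")) {
    paste0(nwk_node_serialize(tree$root, root = TRUE), ";")
  } else {
    stop("cannot serialize object of class ", class(tree)[1], call. = FALSE)
  }
  writeLines(txt, path)
  invisible(path)
}

nwk_node_serialize <- function(node, root = FALSE) {
  body <- if (is.null(node$children)) {
    nwk_quote(node$label)
  } else {
    paste0("(", paste(vapply(node$children, nwk_node_serialize,
                             character(1)), collapse = ","), ")")
  }
  if (root || is.null(node$length)) body
  else paste0(body, ":", nwk_fmt(node$length))
}

#' Read a Newick file
#'
#' Minimal Newick parser supporting single-quoted labels and branch
#' lengths; returns a nested-list tree.
#'
#' @param path Newick file path.
#' @return Object of class \code{newick_tree}: list with \code{root}
#'   (nested nodes with \code{label}/\code{children}/\code{length}) and
#'   \code{leaves} (character vector of leaf labels).
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  txt <- sub(";\\s*$", "", trimws(txt))
  pos <- 1L
  nc <- nchar(txt)
  peek <- function() if (pos <= nc) substr(txt, pos, pos) else ""
  advance <- function() pos <<- pos + 1L
  read_label <- function() {
    if (peek() == "'") {
      advance()
      out <- character(0)
      repeat {
        ch <- peek()
        if (ch == "") stop("unterminated quoted label", call. = FALSE)
        advance()
        if (ch == "'") {
          if (peek() == "'") { out <- c(out, "'"); advance() } else break
        } else out <- c(out, ch)
      }
      paste(out, collapse = "")
    } else {
      start <- pos
      while (pos <= nc && !substr(txt, pos, pos) %in%
             c(",", ")", "(", ":", ";")) advance()
      substr(txt, start, pos - 1L)
    }
  }
  read_length <- function() {
    if (peek() != ":") return(NULL)
    advance()
    start <- pos
    while (pos <= nc && grepl("[-0-9.eE+]", substr(txt, pos, pos))) advance()
    as.numeric(substr(txt, start, pos - 1L))
  }
  parse_node <- function() {
    if (peek() == "(") {
      advance()
      children <- list(parse_node())
      while (peek() == ",") { advance(); children <- c(children, list(parse_node())) }
      if (peek() != ")") stop("expected ')' in newick", call. = FALSE)
      advance()
      lab <- if (!peek() %in% c(":", ",", ")", "", ";")) read_label() else NULL
      list(label = lab, children = children, length = read_length())
    } else {
      list(label = read_label(), children = NULL, length = read_length())
    }
  }
  root <- parse_node()
  collect <- function(node) {
    if (is.null(node$children)) node$label
    else unlist(lapply(node$children, collect))
  }
  structure(list(root = root, leaves = collect(root)),
            class = "newick_tree")
}
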