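#' Bipartite plant-pollinator network
#'
#' Constructs a qualitative (presence/absence) bipartite network from a
#' labelled incidence matrix. Rows are plants (the lower guild), columns are
#' animals (the higher guild). Every species must retain at least one link:
#' species enter a network only through interactions.
#'
#' @param incidence numeric/integer matrix of 0/1 with unique row names
#'   (plants) and column names (animals).
#' @param provenance one of `"diurnal"`, `"nocturnal"`, `"combined"`,
#'   `"synthetic"`, `"resampled"`.
#' @return an object of class `bipartite_network` with elements `plants`,
#'   `animals`, `incidence` (integer matrix) and `provenance`.
#' @export
#' @examples
#' m <- matrix(c(1, 1, 0, 1), 2, 2,
#'             dimnames = list(c("p1", "p2"), c("a1", "a2")))
#' bipartite_network(m, "synthetic")
bipartite_network <- function(incidence,
                              provenance = c("diurnal", "nocturnal",
                                             "combined", "synthetic",
                                             "resampled")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(incidence) || nrow(incidence) < 1L || ncol(incidence) < 1L)
    stop("`incidence` must be a matrix with at least one row and column")
  if (is.null(rownames(incidence)) || is.null(colnames(incidence)))
    stop("`incidence` must carry plant row names and animal column names")
  if (anyDuplicated(rownames(incidence)))
    stop("duplicated plant labels")
  if (anyDuplicated(colnames(incidence)))
    stop("duplicated animal labels")
  if (!all(incidence %in% c(0, 1)))
    stop("`incidence` must contain only 0 and 1")
  mode(incidence) <- "integer"
  if (any(rowSums(incidence) == 0L))
    stop("plant(s) without links: ",
         paste(rownames(incidence)[rowSums(incidence) == 0L], collapse = ", "))
  if (any(colSums(incidence) == 0L))
    stop("animal(s) without links: ",
         paste(colnames(incidence)[colSums(incidence) == 0L], collapse = ", "))
  structure(
    list(plants = rownames(incidence), animals = colnames(incidence),
         incidence = incidence, provenance = provenance),
    class = "bipartite_network"
  )
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf(
    "<bipartite_network: %s> %d plants x %d animals, %d links (connectance %.3f)\n",
    x$provenance, length(x$plants), length(x$animals), n_links(x),
    n_links(x) / (length(x$plants) * length(x$animals))))
  invisible(x)
}

#' Number of links in a network
#' @param net a `bipartite_network`.
#' @return integer link count.
#' @export
n_links <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  sum(net$incidence)
}

# Build a network from a two-column character matrix/data.frame of links.
net_from_links <- function(plants, animals, provenance) {
  stopifnot(length(plants) == length(animals), length(plants) >= 1L)
  pl <- sort(unique(plants))
  an <- sort(unique(animals))
  inc <- matrix(0L, length(pl), length(an), dimnames = list(pl, an))
  inc[cbind(match(plants, pl), match(animals, an))] <- 1L
  bipartite_network(inc, provenance)
}

# Extract the link list (plant, animal) of a network, in row-major order.
links_of <- function(net) {
  idx <- which(net$incidence == 1L, arr.ind = TRUE)
  data.frame(plant_id = net$plants[idx[, 1L]],
             animal_id = net$animals[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' Combine diurnal and nocturnal networks
#'
#' Takes the union of species (keyed by label) and of links. The combined
#' link count satisfies `i_combined <= i_d + i_n`, with equality iff no link
#' is shared. A label used as a plant in one input and as an animal in the
#' other is a guild conflict and an error.
#'
#' @param d,n `bipartite_network` objects (typically diurnal and nocturnal).
#' @return a `bipartite_network` with provenance `"combined"`.
#' @export
combine_networks <- function(d, n) {
  stopifnot(inherits(d, "bipartite_network"), inherits(n, "bipartite_network"))
  conflict <- union(intersect(d$plants, n$animals), intersect(n$plants, d$animals))
  if (length(conflict) > 0L)
    stop("guild conflict: label(s) used as both plant and animal: ",
         paste(conflict, collapse = ", "))
  ld <- links_of(d)
  ln <- links_of(n)
  all_links <- unique(rbind(ld, ln))
  net_from_links(all_links$plant_id, all_links$animal_id, "combined")
}

#' Write a network to CSV
#'
#' @param net a `bipartite_network`.
#' @param path output file path.
#' @param format `"incidence"` writes a labelled incidence matrix (first
#'   column plant labels, header row animal labels); `"edgelist"` writes a
#'   two-column link list.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("incidence", "edgelist")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "bipartite_network"))
  if (format == "incidence") {
    df <- data.frame(plant_id = net$plants, net$incidence,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE)
  } else {
    write.csv(links_of(net), path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network from CSV
#'
#' Inverse of [write_network()]; label order is preserved for the incidence
#' format.
#'
#' @param path CSV path.
#' @param format `"incidence"` or `"edgelist"`.
#' @param provenance provenance tag for the resulting network.
#' @return a `bipartite_network`.
#' @export
read_network <- function(path, format = c("incidence", "edgelist"),
                         provenance = "diurnal") {
  format <- match.arg(format)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "incidence") {
    inc <- as.matrix(df[, -1L, drop = FALSE])
    rownames(inc) <- as.character(df[[1L]])
    mode(inc) <- "integer"
    bipartite_network(inc, provenance)
  } else {
    net_from_links(as.character(df$plant_id), as.character(df$animal_id),
                   provenance)
  }
}
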