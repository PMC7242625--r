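#' Construct and validate a Q-matrix
#'
#' A Q-matrix is the binary item-by-attribute incidence matrix of a
#' diagnostic test: entry \eqn{q_{jk} = 1} means item \eqn{j} requires
#' attribute \eqn{k}. Every item must require at least one attribute.
#'
#' @param entries binary matrix (J items x K attributes), entries in \{0,1\}.
#' @param item_labels optional character vector of item identifiers.
#' @param require_all_attributes if `TRUE`, additionally require every
#'   attribute to be measured by at least one item (enforced for generated
#'   matrices; user-supplied matrices may relax it).
#' @return an object of class `qmatrix`: the integer matrix with attributes
#'   `item_labels` and the per-item count of required attributes `Kj`.
#' @export
qmatrix <- function(entries, item_labels = NULL, require_all_attributes = FALSE) {
  entries <- validate_binary_matrix(entries, "Q-matrix")
  if (any(rowSums(entries) < 1L)) {
    bad <- which(rowSums(entries) < 1L)
    stop("Q-matrix row(s) ", paste(bad, collapse = ", "),
         " require no attribute (all-zero row)")
  }
  if (require_all_attributes && any(colSums(entries) < 1L)) {
    bad <- which(colSums(entries) < 1L)
    stop("Q-matrix attribute(s) ", paste(bad, collapse = ", "),
         " are measured by no item (all-zero column)")
  }
  if (!is.null(item_labels)) {
    stopifnot(length(item_labels) == nrow(entries))
    rownames(entries) <- as.character(item_labels)
  }
  structure(entries, class = c("qmatrix", class(entries)),
            Kj = as.integer(rowSums(entries)))
}

#' Construct a binary response matrix
#'
#' @param entries binary matrix (I examinees x J items), entries in \{0,1\}.
#' @return an integer matrix of class `response_matrix`.
#' @export
response_matrix <- function(entries) {
  entries <- validate_binary_matrix(entries, "response matrix")
  structure(entries, class = c("response_matrix", class(entries)))
}

# shared 0/1 validation used by qmatrix / response_matrix / profile readers
validate_binary_matrix <- function(entries, what) {
  entries <- as.matrix(entries)
  if (!is.numeric(entries)) stop(what, " must be numeric 0/1")
  bad <- which(!(entries %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(entries))
    stop(what, " entry at row ", rc[1L], ", column ", rc[2L],
         " is not 0/1 (value ", entries[bad[1L]], ")")
  }
  storage.mode(entries) <- "integer"
  entries
}

#' Generate a random Q-matrix for a simulation study
#'
#' The first K rows form the K x K identity block, one single-attribute
#' (anchor) item per attribute, so that every attribute is measured by at
#' least one item that requires it alone.  The remaining J - K rows are
#' sampled i.i.d. uniformly, with replacement, from the \eqn{2^K - 1}
#' nonzero attribute vectors.
#'
#' Uses the current R random number stream; call [set.seed()] for
#' reproducibility.
#'
#' @param J number of items (must satisfy `J >= K`).
#' @param K number of attributes.
#' @return a [qmatrix()].
#' @export
generate_qmatrix <- function(J, K) {
  if (length(J) != 1L || length(K) != 1L || J < 1 || K < 1 ||
      J != round(J) || K != round(K))
    stop("J and K must be positive integers")
  if (J < K) stop("test too short to anchor every attribute (J < K)")
  anchors <- diag(1L, K)
  if (J > K) {
    pool <- enumerate_profiles(K)$profiles[-1L, , drop = FALSE] # drop zero vector
    extra <- pool[sample.int(nrow(pool), J - K, replace = TRUE), , drop = FALSE]
    entries <- rbind(anchors, extra)
  } else {
    entries <- anchors
  }
  qmatrix(entries, require_all_attributes = TRUE)
}

#' Q-matrix of the 11-item mixed-number fraction subtraction test
#'
#' The three attributes are (1) borrowing from a whole number,
#' (2) separating a whole number from a fraction, and (3) determining a
#' common denominator. Rows are in item order 1, 2, 3, 4, 5, 6, 8, 9, 10,
#' 11, 13 (item 12 of the original instrument is excluded).
#'
#' @return an 11 x 3 [qmatrix()] with item labels.
#' @export
fraction_subtraction_qmatrix <- function() {
  entries <- matrix(c(
    1, 1, 0,  # item 1
    1, 0, 1,  # item 2
    1, 0, 1,  # item 3
    1, 0, 0,  # item 4
    1, 1, 0,  # item 5
    1, 1, 0,  # item 6
    1, 0, 1,  # item 8
    1, 1, 1,  # item 9
    1, 0, 0,  # item 10
    1, 0, 0,  # item 11
    1, 1, 0   # item 13
  ), ncol = 3L, byrow = TRUE)
  qmatrix(entries,
          item_labels = c(1, 2, 3, 4, 5, 6, 8, 9, 10, 11, 13),
          require_all_attributes = TRUE)
}

#' Enumerate the latent attribute-profile space
#'
#' All \eqn{M = 2^K} binary attribute profiles in the canonical order used
#' throughout the package: binary counting with attribute K as the least
#' significant bit, so for K = 2 the order is (0,0), (0,1), (1,0), (1,1).
#'
#' @param K number of attributes, 1..20.
#' @return a list with `K`, `M`, the `M x K` integer matrix `profiles`, and
#'   `index(profile)`, a function mapping a profile (or matrix of profiles)
#'   to its 1-based canonical index.
#' @export
enumerate_profiles <- function(K) {
  if (length(K) != 1L || K < 1 || K > 20 || K != round(K))
    stop("K must be an integer in 1..20")
  M <- 2L^K
  profiles <- matrix(0L, M, K)
  for (k in seq_len(K))
    profiles[, k] <- rep(rep(0:1, each = 2L^(K - k)), length.out = M)
  pow <- 2L^((K - 1L):0L)
  index <- function(profile) {
    p <- if (is.matrix(profile)) profile else matrix(profile, nrow = 1L)
    as.integer(p %*% pow) + 1L
  }
  list(K = K, M = M, profiles = profiles, index = index)
}

#' Read a binary matrix from CSV
#'
#' Comma-separated 0/1 integers, UTF-8, with an optional single header row
#' (auto-detected: a first row containing any non-numeric token is treated
#' as a header).
#'
#' @param path file path.
#' @param kind `"response"` for an examinee-by-item response matrix,
#'   `"qmatrix"` for an item-by-attribute Q-matrix, `"profiles"` for an
#'   examinee-by-attribute profile matrix.
#' @return a [response_matrix()], [qmatrix()], or plain integer matrix.
#' @export
read_csv_matrix <- function(path, kind = c("response", "qmatrix", "profiles")) {
  kind <- match.arg(kind)
  first <- readLines(path, n = 1L)
  tokens <- strsplit(first, ",", fixed = TRUE)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(tokens)))
  df <- utils::read.csv(path, header = has_header, colClasses = "numeric")
  m <- as.matrix(df)
  dimnames(m) <- NULL
  switch(kind,
         response = response_matrix(m),
         qmatrix  = qmatrix(m),
         profiles = validate_binary_matrix(m, "profile matrix"))
}

#' Write a matrix to CSV (0/1 integers, no row names)
#'
#' @param m matrix.
#' @param path file path.
#' @param header write a column-name header row?
#' @export
write_csv_matrix <- function(m, path, header = FALSE) {
  utils::write.table(as.matrix(m), path, sep = ",", row.names = FALSE,
                     col.names = header, quote = FALSE)
  invisible(path)
}
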