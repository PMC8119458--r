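# Shared expensive fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

shared_corpus <- function() {
  if (is.null(fixture_env$corpus)) {
    fixture_env$corpus <- fixture_corpus(seed = 1L)
  }
  fixture_env$corpus
}

shared_tables <- function() {
  if (is.null(fixture_env$tables)) {
    fixture_env$tables <- build_all_tables(shared_corpus(), seed = 1L)
  }
  fixture_env$tables
}

shared_hairpin <- function() {
  if (is.null(fixture_env$hairpin)) {
    fixture_env$hairpin <- hairpin_toy("GCGCAAGC")
  }
  fixture_env$hairpin
}

hairpin_pairing <- function() {
  pairing_annotation("GCGCAAGC", "((....))", rbind(c(3L, 6L)))
}

# A mode planted at frame_j (partner base fixed at the identity frame),
# expressed in the direction observation libraries store it: libraries
# canonicalize each pair to alphabetical type order, which for
# non-canonical input order transposes the 4 x 4 cross-distance matrix
# and swaps the two local direction vectors.
canonical_mode <- function(frame_j, types = c("G", "C")) {
  fi <- base_frame(c(0, 0, 0), diag(3L))
  d16 <- pair_configuration(fi, frame_j, types)$d16
  if (types[1L] > types[2L]) {
    list(d16 = as.numeric(t(matrix(d16, 4L, 4L))),
         orient = relative_orientation(frame_j, fi))
  } else {
    list(d16 = d16, orient = relative_orientation(fi, frame_j))
  }
}

# random rigid placement helpers used across geometry tests
random_frame <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  base_frame(rnorm(3) * 5,
             rnarefine:::rot_axis(ax, runif(1, 0, 2 * pi)))
}

random_rigid <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  rigid_transform(rnarefine:::rot_axis(ax, runif(1, 0, 2 * pi)),
                  rnorm(3) * 4)
}
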