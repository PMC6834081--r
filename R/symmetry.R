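# Point-group symmetry for Miller-index equivalence.
#
# Merging only needs the rotational point group of the space group: the
# translational parts of the symmetry operators do not change which indices
# are equivalent. Operators act on index columns, h' = M %*% h, and are
# generated by closure from a small generator set per point group.

.pgGenerators <- list(
  "1"   = list(),
  "-1"  = list(-diag(3)),
  "2"   = list(diag(c(-1, 1, -1))),                       # 2-fold along b
  "222" = list(diag(c(-1, -1, 1)), diag(c(1, -1, -1))),
  "4"   = list(matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)), # 4-fold along c
  "422" = list(matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3),
               diag(c(1, -1, -1))),
  "3"   = list(matrix(c(0, -1, 0, 1, -1, 0, 0, 0, 1), 3)),
  "321" = list(matrix(c(0, -1, 0, 1, -1, 0, 0, 0, 1), 3),
               matrix(c(1, -1, 0, 0, -1, 0, 0, 0, -1), 3)),
  "312" = list(matrix(c(0, -1, 0, 1, -1, 0, 0, 0, 1), 3),
               matrix(c(0, -1, 0, -1, 0, 0, 0, 0, -1), 3)),
  "6"   = list(matrix(c(1, -1, 0, 1, 0, 0, 0, 0, 1), 3)),
  "622" = list(matrix(c(1, -1, 0, 1, 0, 0, 0, 0, 1), 3),
               matrix(c(1, -1, 0, 0, -1, 0, 0, 0, -1), 3)),
  "23"  = list(diag(c(-1, -1, 1)), diag(c(1, -1, -1)),
               matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3)),  # 3-fold [111]
  "432" = list(matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3),
               matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3))
)

.sgToPg <- c(
  P1 = "1", `P-1` = "-1",
  P2 = "2", P21 = "2", C2 = "2", I2 = "2",
  P222 = "222", P2221 = "222", P21212 = "222", P212121 = "222",
  C2221 = "222", C222 = "222", F222 = "222", I222 = "222",
  I212121 = "222",
  P4 = "4", P41 = "4", P42 = "4", P43 = "4", I4 = "4", I41 = "4",
  P422 = "422", P4212 = "422", P4122 = "422", P41212 = "422",
  P4222 = "422", P42212 = "422", P4322 = "422", P43212 = "422",
  I422 = "422", I4122 = "422",
  P3 = "3", P31 = "3", P32 = "3", R3 = "3",
  P321 = "321", P3121 = "321", P3221 = "321", R32 = "321",
  P312 = "312", P3112 = "312", P3212 = "312",
  P6 = "6", P61 = "6", P65 = "6", P62 = "6", P64 = "6", P63 = "6",
  P622 = "622", P6122 = "622", P6522 = "622", P6222 = "622",
  P6422 = "622", P6322 = "622",
  P23 = "23", F23 = "23", I23 = "23", P213 = "23", I213 = "23",
  P432 = "432", P4232 = "432", F432 = "432", F4132 = "432",
  I432 = "432", P4332 = "432", P4132 = "432", I4132 = "432"
)

.opKey <- function(m) paste(as.integer(round(m)), collapse = ",")

.closeGroup <- function(gens) {
  ops <- list(diag(3))
  names(ops) <- .opKey(ops[[1]])
  queue <- gens
  while (length(queue)) {
    g <- queue[[1]]
    queue <- queue[-1]
    key <- .opKey(g)
    if (!key %in% names(ops)) {
      ops[[key]] <- g
      # products with everything known so far (and re-queue)
      for (o in ops) {
        queue <- c(queue, list(g %*% o, o %*% g))
      }
    }
  }
  unname(ops)
}

.pgCache <- new.env(parent = emptyenv())

#' Rotational symmetry operators of a space group
#'
#' Returns the point-group rotation matrices (acting on Miller-index
#' columns) of the given space-group symbol. Translational parts are
#' irrelevant for index equivalence and are not represented.
#'
#' @param spaceGroup space-group symbol, e.g. \code{"P1"},
#'   \code{"P212121"}, \code{"P6122"} (spaces ignored, case-insensitive).
#' @return list of 3x3 integer matrices, identity first.
#' @export
symmetryOperators <- function(spaceGroup) {
  sym <- toupper(gsub("[[:space:]()]", "", spaceGroup))
  pg <- .sgToPg[sym]
  if (is.na(pg))
    stop("unknown or unsupported space-group symbol: ", spaceGroup,
         call. = FALSE)
  if (is.null(.pgCache[[pg]]))
    .pgCache[[pg]] <- .closeGroup(.pgGenerators[[pg]])
  .pgCache[[pg]]
}

# Canonical asymmetric-unit representative for each index row.
# Lexicographically largest equivalent (h, then k, then l); with
# anomalous = FALSE the Friedel mates -Mh are included in the orbit.
.mapToAsu <- function(h, k, l, ops, anomalous) {
  if (!anomalous) ops <- c(ops, lapply(ops, function(m) -m))
  bh <- h; bk <- k; bl <- l
  first <- TRUE
  for (m in ops) {
    th <- m[1, 1] * h + m[1, 2] * k + m[1, 3] * l
    tk <- m[2, 1] * h + m[2, 2] * k + m[2, 3] * l
    tl <- m[3, 1] * h + m[3, 2] * k + m[3, 3] * l
    if (first) {
      bh <- th; bk <- tk; bl <- tl
      first <- FALSE
    } else {
      better <- (th > bh) | (th == bh & tk > bk) |
        (th == bh & tk == bk & tl > bl)
      if (any(better)) {
        bh[better] <- th[better]
        bk[better] <- tk[better]
        bl[better] <- tl[better]
      }
    }
  }
  list(h = bh, k = bk, l = bl)
}
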