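# Chinese-restaurant-franchise seating state.
#
# Each experiment (matrix column) is one restaurant row; its customers are the
# N gene-expression values of that experiment. Customers sit at tables, tables
# serve dishes from a global menu shared across rows; the dish of a customer's
# table is its cluster membership. Tables and dishes carry the sufficient
# statistics (n, sum, sumsq) of the values assigned to them so that collapsed
# predictive densities are O(1).
#
# Representation (list of class "seating_state"):
#   phi        M x N integer matrix, phi[j,i] = table label of customer (j,i),
#              NA while a customer is temporarily unseated
#   tab_dish   list over rows; named integer vector, table label -> dish label
#              (NA for a table whose dish is being resampled)
#   tab_n, tab_sum, tab_sumsq   parallel named vectors of table statistics
#   dish_tab   named integer vector, dish label -> number of tables serving it
#              (summed over rows, i.e. sum_j d_jk)
#   dish_n, dish_sum, dish_sumsq  dish-level data statistics
#   next_table integer vector (fresh table label per row), next_dish integer
#
# Labels are arbitrary positive integers drawn from monotone counters and are
# garbage-collected when a table empties or a dish loses its last table.

new_seating_state <- function(M, N) {
  structure(list(
    phi = matrix(NA_integer_, M, N),
    tab_dish = rep(list(integer(0)), M),
    tab_n = rep(list(integer(0)), M),
    tab_sum = rep(list(numeric(0)), M),
    tab_sumsq = rep(list(numeric(0)), M),
    dish_tab = integer(0),
    dish_n = integer(0),
    dish_sum = numeric(0),
    dish_sumsq = numeric(0),
    next_table = rep(1L, M),
    next_dish = 1L
  ), class = "seating_state")
}

st_dim <- function(state) dim(state$phi)

# drop a dish that no table serves any more
st_gc_dish <- function(state, k) {
  key <- as.character(k)
  state$dish_tab <- state$dish_tab[names(state$dish_tab) != key]
  state$dish_n <- state$dish_n[names(state$dish_n) != key]
  state$dish_sum <- state$dish_sum[names(state$dish_sum) != key]
  state$dish_sumsq <- state$dish_sumsq[names(state$dish_sumsq) != key]
  state
}

# remove customer (j,i) with value g from its table and dish
st_unseat <- function(state, j, i, g) {
  t <- state$phi[j, i]
  if (is.na(t)) stop("customer already unseated")
  tk <- as.character(t)
  k <- state$tab_dish[[j]][[tk]]
  kk <- as.character(k)
  state$phi[j, i] <- NA_integer_
  state$tab_n[[j]][[tk]] <- state$tab_n[[j]][[tk]] - 1L
  state$tab_sum[[j]][[tk]] <- state$tab_sum[[j]][[tk]] - g
  state$tab_sumsq[[j]][[tk]] <- state$tab_sumsq[[j]][[tk]] - g^2
  state$dish_n[[kk]] <- state$dish_n[[kk]] - 1L
  state$dish_sum[[kk]] <- state$dish_sum[[kk]] - g
  state$dish_sumsq[[kk]] <- state$dish_sumsq[[kk]] - g^2
  if (state$tab_n[[j]][[tk]] == 0L) {
    keep <- names(state$tab_dish[[j]]) != tk
    state$tab_dish[[j]] <- state$tab_dish[[j]][keep]
    state$tab_n[[j]] <- state$tab_n[[j]][keep]
    state$tab_sum[[j]] <- state$tab_sum[[j]][keep]
    state$tab_sumsq[[j]] <- state$tab_sumsq[[j]][keep]
    state$dish_tab[[kk]] <- state$dish_tab[[kk]] - 1L
    if (state$dish_tab[[kk]] == 0L) state <- st_gc_dish(state, k)
  }
  state
}

# seat customer (j,i) with value g at existing table t of row j
st_seat_existing <- function(state, j, i, t, g) {
  tk <- as.character(t)
  if (!tk %in% names(state$tab_dish[[j]])) stop("no such table in row ", j, ": ", t)
  k <- state$tab_dish[[j]][[tk]]
  kk <- as.character(k)
  state$phi[j, i] <- as.integer(t)
  state$tab_n[[j]][[tk]] <- state$tab_n[[j]][[tk]] + 1L
  state$tab_sum[[j]][[tk]] <- state$tab_sum[[j]][[tk]] + g
  state$tab_sumsq[[j]][[tk]] <- state$tab_sumsq[[j]][[tk]] + g^2
  state$dish_n[[kk]] <- state$dish_n[[kk]] + 1L
  state$dish_sum[[kk]] <- state$dish_sum[[kk]] + g
  state$dish_sumsq[[kk]] <- state$dish_sumsq[[kk]] + g^2
  state
}

# open a fresh (dishless) table in row j holding customer (j,i); the caller
# must immediately assign it a dish with st_assign_table_dish()
st_open_table <- function(state, j, i, g) {
  t <- state$next_table[j]
  state$next_table[j] <- t + 1L
  tk <- as.character(t)
  state$phi[j, i] <- t
  state$tab_dish[[j]][[tk]] <- NA_integer_
  state$tab_n[[j]][[tk]] <- 1L
  state$tab_sum[[j]][[tk]] <- g
  state$tab_sumsq[[j]][[tk]] <- g^2
  state
}

# detach table (j,t)'s block of data from its dish (for dish resampling);
# the table keeps its customers but its dish becomes NA
st_detach_table <- function(state, j, t) {
  tk <- as.character(t)
  k <- state$tab_dish[[j]][[tk]]
  if (is.na(k)) return(state)
  kk <- as.character(k)
  state$dish_tab[[kk]] <- state$dish_tab[[kk]] - 1L
  state$dish_n[[kk]] <- state$dish_n[[kk]] - state$tab_n[[j]][[tk]]
  state$dish_sum[[kk]] <- state$dish_sum[[kk]] - state$tab_sum[[j]][[tk]]
  state$dish_sumsq[[kk]] <- state$dish_sumsq[[kk]] - state$tab_sumsq[[j]][[tk]]
  state$tab_dish[[j]][[tk]] <- NA_integer_
  if (state$dish_tab[[kk]] == 0L) state <- st_gc_dish(state, k)
  state
}

# give table (j,t) dish k (existing label) or a fresh dish (k = NA)
st_assign_table_dish <- function(state, j, t, k = NA) {
  tk <- as.character(t)
  if (is.na(k)) {
    k <- state$next_dish
    state$next_dish <- k + 1L
    kk <- as.character(k)
    state$dish_tab[[kk]] <- 0L
    state$dish_n[[kk]] <- 0L
    state$dish_sum[[kk]] <- 0
    state$dish_sumsq[[kk]] <- 0
  }
  kk <- as.character(k)
  if (!kk %in% names(state$dish_tab)) stop("no such dish: ", k)
  state$tab_dish[[j]][[tk]] <- as.integer(k)
  state$dish_tab[[kk]] <- state$dish_tab[[kk]] + 1L
  state$dish_n[[kk]] <- state$dish_n[[kk]] + state$tab_n[[j]][[tk]]
  state$dish_sum[[kk]] <- state$dish_sum[[kk]] + state$tab_sum[[j]][[tk]]
  state$dish_sumsq[[kk]] <- state$dish_sumsq[[kk]] + state$tab_sumsq[[j]][[tk]]
  state
}

# dish label matrix z[j,i] = dish of customer (j,i)'s table
st_dish_matrix <- function(state) {
  d <- st_dim(state)
  z <- matrix(NA_integer_, d[1L], d[2L])
  for (j in seq_len(d[1L])) {
    map <- state$tab_dish[[j]]
    z[j, ] <- as.integer(map[as.character(state$phi[j, ])])
  }
  z
}

#' Initialize the franchise seating state
#'
#' Builds a valid starting configuration for the Gibbs sampler over the
#' Chinese-restaurant-franchise representation.
#'
#' Modes:
#' * `"each-own-table"`: every customer opens its own table; all tables of a
#'   row share one row-specific dish (the configuration used by the package's
#'   worked example).
#' * `"single-table"`: one table per row holding all the row's customers; all
#'   rows share one dish.
#' * `"random"`: each customer picks a table uniformly from `N` candidate
#'   labels per row; each resulting table picks a dish uniformly from as many
#'   candidate dishes as there are tables. Empty tables/dishes are dropped.
#'
#' @param data an [expression_matrix()].
#' @param mode initialization mode, see Details.
#' @param seed optional integer seed (only the `"random"` mode draws).
#' @return a `seating_state`.
#' @export
init_state <- function(data, mode = c("each-own-table", "single-table", "random"),
                       seed = NULL) {
  data <- as_expression_matrix(data)
  mode <- match.arg(mode)
  N <- nrow(data); M <- ncol(data)
  state <- new_seating_state(M, N)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "each-own-table") {
    for (j in seq_len(M)) {
      state <- st_open_table(state, j, 1L, data[1L, j])
      t1 <- state$phi[j, 1L]
      state <- st_assign_table_dish(state, j, t1, NA)
      k <- state$tab_dish[[j]][[as.character(t1)]]
      if (N > 1L) for (i in 2L:N) {
        state <- st_open_table(state, j, i, data[i, j])
        state <- st_assign_table_dish(state, j, state$phi[j, i], k)
      }
    }
  } else if (mode == "single-table") {
    shared_dish <- NA
    for (j in seq_len(M)) {
      state <- st_open_table(state, j, 1L, data[1L, j])
      t1 <- state$phi[j, 1L]
      if (N > 1L) for (i in 2L:N) state <- st_seat_at_dishless(state, j, i, t1, data[i, j])
      state <- st_assign_table_dish(state, j, t1, shared_dish)
      if (is.na(shared_dish)) shared_dish <- state$tab_dish[[j]][[as.character(t1)]]
    }
  } else {
    for (j in seq_len(M)) {
      draw <- sample.int(N, N, replace = TRUE)
      labs <- sort(unique(draw))
      for (lab in labs) {
        members <- which(draw == lab)
        i1 <- members[1L]
        state <- st_open_table(state, j, i1, data[i1, j])
        t <- state$phi[j, i1]
        for (i in members[-1L]) state <- st_seat_at_dishless(state, j, i, t, data[i, j])
      }
    }
    # uniform dish choice over as many candidates as tables in total
    ntab <- sum(vapply(state$tab_dish, length, 1L))
    ddraw <- sample.int(ntab, ntab, replace = TRUE)
    pos <- 0L
    dish_of_draw <- rep(NA_integer_, ntab)
    for (j in seq_len(M)) {
      for (tk in names(state$tab_dish[[j]])) {
        pos <- pos + 1L
        lab <- ddraw[pos]
        if (is.na(dish_of_draw[lab])) {
          state <- st_assign_table_dish(state, j, as.integer(tk), NA)
          dish_of_draw[lab] <- state$tab_dish[[j]][[tk]]
        } else {
          state <- st_assign_table_dish(state, j, as.integer(tk), dish_of_draw[lab])
        }
      }
    }
  }
  state
}

# seat customer at a table that may not have a dish yet (init-time helper)
st_seat_at_dishless <- function(state, j, i, t, g) {
  tk <- as.character(t)
  k <- state$tab_dish[[j]][[tk]]
  state$phi[j, i] <- as.integer(t)
  state$tab_n[[j]][[tk]] <- state$tab_n[[j]][[tk]] + 1L
  state$tab_sum[[j]][[tk]] <- state$tab_sum[[j]][[tk]] + g
  state$tab_sumsq[[j]][[tk]] <- state$tab_sumsq[[j]][[tk]] + g^2
  if (!is.na(k)) {
    kk <- as.character(k)
    state$dish_n[[kk]] <- state$dish_n[[kk]] + 1L
    state$dish_sum[[kk]] <- state$dish_sum[[kk]] + g
    state$dish_sumsq[[kk]] <- state$dish_sumsq[[kk]] + g^2
  }
  state
}

#' Validate a seating state against its data
#'
#' Recomputes every counter and sufficient statistic from the raw assignments
#' and reports all invariant violations: customers seated exactly once per
#' row, no zero-count tables or unserved dishes retained, dish table-counts
#' equal to the number of tables serving each dish, and table/dish statistics
#' consistent with the data.
#'
#' @param state a `seating_state`.
#' @param data the [expression_matrix()] the state refers to.
#' @return character vector of violation messages; empty if consistent.
#' @export
validate_state <- function(state, data) {
  data <- as_expression_matrix(data)
  N <- nrow(data); M <- ncol(data)
  out <- character(0)
  bad <- function(...) out <<- c(out, sprintf(...))
  d <- st_dim(state)
  if (d[1L] != M || d[2L] != N) {
    return(sprintf("dimension mismatch: state is %d x %d, data needs %d x %d",
                   d[1L], d[2L], M, N))
  }
  tol <- 1e-8
  dish_tab_re <- integer(0); dish_n_re <- integer(0)
  dish_sum_re <- numeric(0); dish_sumsq_re <- numeric(0)
  for (j in seq_len(M)) {
    if (anyNA(state$phi[j, ])) bad("row %d: unseated customer", j)
    seated <- state$phi[j, !is.na(state$phi[j, ])]
    occ <- table(as.character(seated))
    tabs <- names(state$tab_dish[[j]])
    if (sum(state$tab_n[[j]]) != sum(!is.na(state$phi[j, ])))
      bad("row %d: customer count (sum c_jt = %d, seated = %d)",
          j, sum(state$tab_n[[j]]), sum(!is.na(state$phi[j, ])))
    for (tk in tabs) {
      members <- which(!is.na(state$phi[j, ]) & as.character(state$phi[j, ]) == tk)
      if (state$tab_n[[j]][[tk]] == 0L) bad("row %d: zero-count table %s retained", j, tk)
      if (length(members) != state$tab_n[[j]][[tk]])
        bad("row %d table %s: c_jt = %d but %d customers point at it",
            j, tk, state$tab_n[[j]][[tk]], length(members))
      vals <- data[members, j]
      if (abs(sum(vals) - state$tab_sum[[j]][[tk]]) > tol ||
          abs(sum(vals^2) - state$tab_sumsq[[j]][[tk]]) > tol)
        bad("row %d table %s: stale sufficient statistics", j, tk)
      k <- state$tab_dish[[j]][[tk]]
      if (is.na(k)) {
        bad("row %d table %s: no dish assigned", j, tk)
      } else {
        kk <- as.character(k)
        dish_tab_re[kk] <- (if (kk %in% names(dish_tab_re)) dish_tab_re[[kk]] else 0L) + 1L
        dish_n_re[kk] <- (if (kk %in% names(dish_n_re)) dish_n_re[[kk]] else 0L) + length(members)
        dish_sum_re[kk] <- (if (kk %in% names(dish_sum_re)) dish_sum_re[[kk]] else 0) + sum(vals)
        dish_sumsq_re[kk] <- (if (kk %in% names(dish_sumsq_re)) dish_sumsq_re[[kk]] else 0) + sum(vals^2)
      }
    }
    stray <- setdiff(names(occ), tabs)
    if (length(stray)) bad("row %d: customers at unknown table(s) %s", j, paste(stray, collapse = ","))
  }
  if (!setequal(names(state$dish_tab), names(dish_tab_re))) {
    extra <- setdiff(names(state$dish_tab), names(dish_tab_re))
    if (length(extra)) bad("unserved dish(es) retained: %s", paste(extra, collapse = ","))
    missing <- setdiff(names(dish_tab_re), names(state$dish_tab))
    if (length(missing)) bad("dish(es) missing from menu: %s", paste(missing, collapse = ","))
  }
  for (kk in intersect(names(state$dish_tab), names(dish_tab_re))) {
    if (state$dish_tab[[kk]] != dish_tab_re[[kk]])
      bad("dish %s: table count %d, recomputed %d", kk, state$dish_tab[[kk]], dish_tab_re[[kk]])
    if (state$dish_n[[kk]] != dish_n_re[[kk]] ||
        abs(state$dish_sum[[kk]] - dish_sum_re[[kk]]) > tol ||
        abs(state$dish_sumsq[[kk]] - dish_sumsq_re[[kk]]) > tol)
      bad("dish %s: stale data statistics", kk)
  }
  out
}

#' @export
print.seating_state <- function(x, ...) {
  d <- st_dim(x)
  K <- length(x$dish_tab)
  ntab <- sum(vapply(x$tab_dish, length, 1L))
  cat(sprintf("seating_state: %d rows x %d customers, %d tables, %d dishes\n",
              d[1L], d[2L], ntab, K))
  invisible(x)
}

# number of distinct dishes currently served
n_dishes <- function(state) length(state$dish_tab)
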