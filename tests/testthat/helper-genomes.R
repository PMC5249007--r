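# shared helpers: terse constructors for fixtures built in code

# genome from circular gene order(s)
go <- function(...) adjacencies_from_gene_order(list(...))

# order-insensitive adjacency "set" of end-label pairs, for oracle-style
# set intersections independent of the package's internal keys
adj_set <- function(g) {
  apply(g$adj, 1L, function(r) paste(sort(end_label(r)), collapse = "-"))
}

# canonical single string identifying a genome (for equality checks)
genome_id <- function(g) paste(sort(adj_set(g)), collapse = ";")
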