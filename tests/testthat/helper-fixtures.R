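# Small analytic graph fixtures with hand-computable metrics.

triangle <- function()
  make_net(adj_from_edges(3, rbind(c(1, 2), c(2, 3), c(1, 3))))

path3 <- function()
  make_net(adj_from_edges(3, rbind(c(1, 2), c(2, 3))))

star5 <- function()
  make_net(adj_from_edges(5, cbind(1, 2:5)))

k4 <- function()
  make_net(adj_from_edges(4, t(utils::combn(4, 2))))

# A-B-C-D cycle plus chord A-C
chorded_cycle <- function()
  make_net(adj_from_edges(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4),
                                   c(1, 3))))

two_triangles <- function()
  make_net(adj_from_edges(6, rbind(c(1, 2), c(2, 3), c(1, 3),
                                   c(4, 5), c(5, 6), c(4, 6))))
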