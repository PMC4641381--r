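a
about
after
all
also
an
and
are
as
at
be
been
between
both
but
by
can
could
did
do
does
for
from
had
has
have
here
how
if
in
into
is
it
its
may
more
most
no
not
of
on
one
only
or
other
our
out
over
should
so
some
such
than
that
the
their
then
there
these
they
this
through
to
under
up
use
used
using
was
we
were
what
when
which
while
who
will
with
within
would
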