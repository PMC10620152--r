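a
an
and
are
as
at
by
for
from
in
into
is
it
of
on
or
the
to
with
contains
contain
ingredient
ingredients
may
trace
traces
added
include
includes
including
less
than
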