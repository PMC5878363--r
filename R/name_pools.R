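# Fixed name pools for the synthetic identity generator. Small, packaged
# lists are sufficient: realistic collision rates come from the pools being
# finite, and the nickname map feeds the nickname-substitution error.

.first_names_male <- c(
  "James", "John", "Robert", "Michael", "William", "David", "Richard",
  "Joseph", "Thomas", "Charles", "Christopher", "Daniel", "Matthew",
  "Anthony", "Donald", "Mark", "Paul", "Steven", "Andrew", "Kenneth",
  "George", "Joshua", "Kevin", "Brian", "Edward", "Ronald", "Timothy",
  "Jason", "Jeffrey", "Ryan", "Jacob", "Gary", "Nicholas", "Eric",
  "Jonathan", "Stephen", "Larry", "Justin", "Scott", "Brandon", "Benjamin",
  "Samuel", "Gregory", "Frank", "Alexander", "Raymond", "Patrick", "Jack",
  "Dennis", "Jerry", "Tyler", "Aaron", "Jose", "Henry", "Adam", "Douglas",
  "Nathan", "Peter", "Zachary", "Kyle", "Walter", "Harold", "Jeremy",
  "Ethan", "Carl", "Keith", "Roger", "Gerald", "Terry", "Sean", "Arthur",
  "Austin", "Noah", "Lawrence", "Jesse", "Joe", "Bryan", "Billy", "Jordan",
  "Albert", "Dylan", "Bruce", "Willie", "Gabriel", "Alan", "Juan", "Logan",
  "Wayne", "Ralph", "Roy", "Eugene", "Randy", "Vincent", "Russell", "Louis",
  "Philip", "Bobby", "Johnny", "Bradley", "Marcus", "Darnell", "Tyrone",
  "Andre", "Lamar", "Malik", "Terrence", "Dwayne", "Reginald", "Cedric"
)

.first_names_female <- c(
  "Mary", "Patricia", "Jennifer", "Linda", "Elizabeth", "Barbara", "Susan",
  "Jessica", "Sarah", "Karen", "Nancy", "Lisa", "Margaret", "Betty",
  "Sandra", "Ashley", "Dorothy", "Kimberly", "Emily", "Donna", "Michelle",
  "Carol", "Amanda", "Melissa", "Deborah", "Stephanie", "Rebecca", "Laura",
  "Sharon", "Cynthia", "Kathleen", "Amy", "Shirley", "Angela", "Helen",
  "Anna", "Brenda", "Pamela", "Nicole", "Ruth", "Katherine", "Samantha",
  "Christine", "Emma", "Catherine", "Debra", "Virginia", "Rachel",
  "Carolyn", "Janet", "Maria", "Heather", "Diane", "Julie", "Joyce",
  "Victoria", "Kelly", "Christina", "Joan", "Evelyn", "Lauren", "Judith",
  "Olivia", "Frances", "Martha", "Cheryl", "Megan", "Andrea", "Hannah",
  "Jacqueline", "Ann", "Jean", "Alice", "Gloria", "Teresa", "Doris", "Sara",
  "Janice", "Julia", "Marie", "Grace", "Denise", "Amber", "Danielle",
  "Theresa", "Sophia", "Marilyn", "Diana", "Brittany", "Natalie", "Isabella",
  "Charlotte", "Rose", "Alexis", "Kayla", "Tamika", "Latoya", "Keisha",
  "Shanice", "Ebony", "Jasmine", "Aisha", "Monique", "Chantel", "Renee"
)

.last_names <- c(
  "Smith", "Johnson", "Williams", "Brown", "Jones", "Garcia", "Miller",
  "Davis", "Rodriguez", "Martinez", "Hernandez", "Lopez", "Gonzalez",
  "Wilson", "Anderson", "Thomas", "Taylor", "Moore", "Jackson", "Martin",
  "Lee", "Perez", "Thompson", "White", "Harris", "Sanchez", "Clark",
  "Ramirez", "Lewis", "Robinson", "Walker", "Young", "Allen", "King",
  "Wright", "Scott", "Torres", "Nguyen", "Hill", "Flores", "Green",
  "Adams", "Nelson", "Baker", "Hall", "Rivera", "Campbell", "Mitchell",
  "Carter", "Roberts", "Gomez", "Phillips", "Evans", "Turner", "Diaz",
  "Parker", "Cruz", "Edwards", "Collins", "Reyes", "Stewart", "Morris",
  "Morales", "Murphy", "Cook", "Rogers", "Gutierrez", "Ortiz", "Morgan",
  "Cooper", "Peterson", "Bailey", "Reed", "Kelly", "Howard", "Ramos",
  "Kim", "Cox", "Ward", "Richardson", "Watson", "Brooks", "Chavez",
  "Wood", "James", "Bennett", "Gray", "Mendoza", "Ruiz", "Hughes", "Price",
  "Alvarez", "Castillo", "Sanders", "Patel", "Myers", "Long", "Ross",
  "Foster", "Jimenez", "Washington", "Butler", "Simmons", "Gibson",
  "Bryant", "Alexander", "Russell", "Griffin", "Hayes", "Coleman",
  "Henderson", "O'Brien", "O'Connor", "McCarthy", "St. Clair",
  "Washington-Lee", "Del Rio", "Van Dyke", "De la Cruz", "Abara", "Mensah",
  "Okafor", "Diallo", "Jean-Baptiste"
)

.nickname_map <- c(
  William = "Bill", Robert = "Bob", Richard = "Dick", James = "Jim",
  John = "Jack", Michael = "Mike", Christopher = "Chris", Joseph = "Joe",
  Thomas = "Tom", Charles = "Chuck", Daniel = "Dan", Matthew = "Matt",
  Anthony = "Tony", Steven = "Steve", Andrew = "Drew", Kenneth = "Ken",
  Edward = "Ed", Timothy = "Tim", Jeffrey = "Jeff", Nicholas = "Nick",
  Benjamin = "Ben", Samuel = "Sam", Gregory = "Greg", Alexander = "Alex",
  Patrick = "Pat", Elizabeth = "Liz", Margaret = "Peggy", Patricia = "Pat",
  Jennifer = "Jen", Katherine = "Kate", Kimberly = "Kim", Deborah = "Deb",
  Rebecca = "Becky", Kathleen = "Kathy", Pamela = "Pam", Christine = "Chris",
  Jacqueline = "Jackie", Victoria = "Vicky", Jessica = "Jess",
  Stephanie = "Steph", Samantha = "Sam", Catherine = "Cathy"
)

.cohort_sites <- sprintf("CS%02d", 1:13)
.external_sites <- sprintf("EX%02d", 1:20)
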